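#!/usr/bin/env Rscript
# Opt-in genome-scale benchmark driver.  Requires a locally downloaded GEM
# (BiGG JSON, e.g. iJO1366.json) and a core-definition file; both are large
# downloads and the MILP enumeration takes minutes to hours, so this script
# is not part of the test suite.
#
# Usage:
#   Rscript scripts/gem_benchmarks.R --model iJO1366.json \
#       --core core_reactions.txt [--targets his__L_c,dttp_c] \
#       [--uptake EX_glc__D_e=10] [--max-alternatives 50] [--out bench.json]
#
# core_reactions.txt: one reaction id per line; lines starting with '#' are
# comments.  Metabolite ids listed after a '+' prefix are added to the core
# metabolite set (cofactor pairs, inorganics).

suppressPackageStartupMessages(library(lumpnet))

args <- commandArgs(trailingOnly = TRUE)
getopt <- function(flag, default = NULL) {
  k <- match(flag, args)
  if (is.na(k) || k == length(args)) return(default)
  args[k + 1]
}
model_path <- getopt("--model")
core_path <- getopt("--core")
if (is.null(model_path) || is.null(core_path)) {
  stop("need --model <gem.json> and --core <core_reactions.txt>")
}
targets_arg <- getopt("--targets")
max_alt <- as.integer(getopt("--max-alternatives", "50"))
out <- getopt("--out", "benchmark_results.json")

model <- load_model(model_path)
core_lines <- trimws(readLines(core_path))
core_lines <- core_lines[nzchar(core_lines) & !startsWith(core_lines, "#")]
extra_mets <- sub("^\\+", "", core_lines[startsWith(core_lines, "+")])
core_ids <- core_lines[!startsWith(core_lines, "+")]

uptake <- getopt("--uptake")
if (!is.null(uptake)) {
  kv <- strsplit(uptake, "=")[[1]]
  model <- set_medium(model, stats::setNames(as.numeric(kv[2]), kv[1]))
}

composition <- parse_biomass(model)
mu_max <- fba(model)$objective_value
message(sprintf("parent model mu_max = %.4g/h; %d biomass building blocks",
                mu_max, nrow(composition$entries)))

targets <- if (!is.null(targets_arg)) {
  strsplit(targets_arg, ",")[[1]]
} else {
  composition$entries$bbb_id[composition$entries$role == "consumed"]
}
roles <- ifelse(
  targets %in% composition$entries$bbb_id[composition$entries$role ==
                                            "produced"],
  "produced", "consumed")
model <- add_target_sinks(model, targets, role = roles)
partition <- define_core(model, core_ids,
                         extra_core_metabolites = extra_mets)

nj <- stats::setNames(composition$entries$n_j, composition$entries$bbb_id)
demands <- stats::setNames(
  ifelse(targets %in% names(nj), nj[targets] * mu_max, 1e-3),
  paste0("sink_", targets))

res <- generate_lumps(model, partition, demands, max_count = max_alt)

summary <- lapply(names(res), function(sid) {
  r <- res[[sid]]
  list(target = sub("^sink_", "", sid),
       status = r$status,
       s_min = if (length(r$subnetworks)) r$subnetworks[[1]]$size else NA,
       n_alternatives = length(r$subnetworks),
       n_unique_lumps = length(r$lumps),
       lumps = vapply(r$lumps, lump_equation, character(1)))
})
jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA)
message(sprintf("wrote %s", out))
for (s in summary) {
  message(sprintf("%-14s %-8s S_min=%s alternatives=%d unique_lumps=%d",
                  s$target, s$status, s$s_min, s$n_alternatives,
                  s$n_unique_lumps))
}
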