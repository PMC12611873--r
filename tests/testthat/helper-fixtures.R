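# Shared fixtures. The fitted-model fixture is built once per test run and
# cached; it uses a scaled-down committee/CV design so module tests stay
# fast. Study-condition fits (full design) live in the acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

fixture_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  cfg <- pipeline_config(
    seed = 11,
    occurrence = list(n_splits = 20),
    abundance = list(repeats = 3),
    projection = list(n_boot = 200))
  .fixture_env$fit <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  .fixture_env$fit
}

# Small separable presence table: presence iff substrate above 50.
separable_presence_table <- function(n = 40, seed = 5) {
  set.seed(seed)
  sub <- c(runif(n / 2, 0, 40), runif(n / 2, 60, 100))
  data.frame(substrate_cover = sub,
             min_salinity = runif(n, 8, 25),
             exposure = rlnorm(n, 9, 1),
             presence = sub > 50)
}

# Brute-force AUC: pairwise concordance with ties counted one half.
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
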