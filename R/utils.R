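# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Split n indices into chunks of size k, last chunk of size n %% k if nonzero.
chunk_sizes <- function(n, k) {
  stopifnot(n >= 1, k >= 1)
  n_full <- n %/% k
  rem <- n %% k
  c(rep(k, n_full), if (rem > 0) rem)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Provenance sidecar: every file-producing step records what made it.
write_provenance <- function(path, step, params) {
  prov <- list(
    package = "orthocell",
    version = as.character(utils::packageVersion("orthocell")),
    step = step,
    params = params
  )
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

abbrev_ids <- function(ids, n = 5) {
  if (length(ids) <= n) paste(ids, collapse = ", ")
  else paste0(paste(ids[seq_len(n)], collapse = ", "),
              ", ... (", length(ids), " total)")
}
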