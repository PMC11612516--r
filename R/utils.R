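# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` means "use the current
# stream" (no save/restore).
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Stable short hash of an R object (polynomial rolling hash over its deparse).
# Used only to stamp output files so a rerun with the same configuration is
# recognizable; not cryptographic.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

output_header <- function(seed = NULL, cfg_hash = NULL) {
  c(
    sprintf("# poolscan %s", as.character(utils::packageVersion("poolscan"))),
    if (!is.null(cfg_hash)) sprintf("# config %s", cfg_hash),
    if (!is.null(seed)) sprintf("# seed %s", format(seed, scientific = FALSE))
  )
}

write_tsv_commented <- function(df, path, comments = output_header()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comments, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
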