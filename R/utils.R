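# Internal helpers shared across modules.

coremk_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("coremk_", class), "coremk_error"), ...)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state so callers' RNG streams are unaffected. With
#' `seed = NULL` the code runs against the current state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Codon-string matrix (n_seq x n_codons) from a single-character matrix.
codon_strings <- function(mat) {
  stopifnot(ncol(mat) %% 3L == 0L)
  i1 <- seq(1L, ncol(mat), by = 3L)
  out <- matrix(paste0(mat[, i1], mat[, i1 + 1L], mat[, i1 + 2L]),
    nrow = nrow(mat)
  )
  rownames(out) <- rownames(mat)
  out
}

# Strict-majority element of a character vector, or NA if none.
strict_majority <- function(x) {
  if (length(x) == 1L) {
    return(x)
  }
  tab <- table(x)
  top <- max(tab)
  if (top * 2L <= length(x)) {
    return(NA_character_)
  }
  # ties cannot occur for a strict majority
  names(tab)[which.max(tab)]
}

# Most frequent element; ties broken by lexicographic order.
modal_value <- function(x) {
  tab <- table(x)
  cand <- names(tab)[tab == max(tab)]
  sort(cand)[1L]
}

is_acgt <- function(x) x %in% c("A", "C", "G", "T")
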