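#' @importFrom rlang abort warn .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join across n
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr imap
NULL

# scalar checks used throughout; `what` names the offending quantity in errors
check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive and finite.", what))
  }
  invisible(x)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative and finite.", what))
  }
  invisible(x)
}

# forward-looking windowed minimum: out[i] = min(x[i .. min(i+w-1, n)]).
# Block prefix/suffix cummin trick; O(n) and fully vectorized. With block
# size w, the window [i, i+w-1] spans at most two adjacent blocks, so its
# minimum is min(suffix-min at i, prefix-min at i+w-1).
roll_min_forward <- function(x, w) {
  n <- length(x)
  if (w <= 1L) return(x)
  if (w >= n) return(rep(min(x), n))
  blk <- (seq_len(n) - 1L) %/% w
  pref <- stats::ave(x, blk, FUN = cummin)
  suff <- stats::ave(x, blk, FUN = function(v) rev(cummin(rev(v))))
  j <- pmin(seq_len(n) + w - 1L, n)
  pmin(suff, pref[j])
}

# local seed handling: restores the caller's RNG state on exit
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
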