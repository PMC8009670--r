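# Small numerical helpers shared across modules.

#' Centered moving average
#'
#' Moving average with a centered window; edges are averaged over the
#' available samples so the output has no NA padding and the same length
#' as the input.
#'
#' @param x numeric vector.
#' @param k window width in samples (coerced to an odd integer >= 1).
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < 3L) return(x)
  k <- min(k, if (length(x) %% 2L == 1L) length(x) else length(x) - 1L)
  cs <- cumsum(c(0, x))
  n <- length(x)
  h <- (k - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Quantile function of a lower-truncated normal
#'
#' @param u probabilities in (0, 1).
#' @param mean,sd mean and SD of the untruncated normal.
#' @param lower truncation point (values are conditioned on exceeding it).
#' @keywords internal
qtnorm_lower <- function(u, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(max(mean, lower), length(u)))
  a <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(a + u * (1 - a))
}

#' Structured per-cell log message
#'
#' Emits a classed condition carrying the cell context, so callers can
#' capture or silence pipeline progress without parsing strings.
#' @keywords internal
pq_log <- function(msg, cell_id = NA_character_, stage = NA_character_) {
  cond <- structure(
    class = c("picquant_log", "message", "condition"),
    list(message = paste0("[", stage, if (!is.na(cell_id)) paste0(":", cell_id), "] ", msg, "\n"),
         call = NULL, cell_id = cell_id, stage = stage)
  )
  message(cond)
  invisible(NULL)
}

#' Stop with a classed picquant error
#' @keywords internal
pq_stop <- function(msg, class) {
  stop(structure(class = c(class, "picquant_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Derive a reproducible 32-bit sub-seed from a parent seed and an index.
# Arithmetic in doubles (exact below 2^53) to avoid integer overflow.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483587)
}
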