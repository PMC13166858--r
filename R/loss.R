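#' Binary cross-entropy loss
#'
#' `-sum(y * log(p) + (1 - y) * log(1 - p))` in its printed sum form, or the
#' mean-reduced variant used by the trainer (so gradient accumulation over
#' equal mini-batches is exactly equivalent to one large batch).
#' Probabilities are clamped to `[eps, 1 - eps]` before taking logs.
#'
#' @param y Binary labels (0/1).
#' @param p Predicted probabilities in (0, 1).
#' @param reduction `"sum"` (default) or `"mean"`.
#' @param eps Clamping constant (default 1e-12).
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' bce_loss(1, 0.5)                         # log(2)
#' bce_loss(c(1, 0), c(0.8, 0.3))           # -(log(0.8) + log(0.7))
bce_loss <- function(y, p, reduction = c("sum", "mean"), eps = 1e-12) {
  reduction <- match.arg(reduction)
  if (length(y) != length(p)) abort("`y` and `p` must have equal length.")
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1.")
  p <- pmin(pmax(p, eps), 1 - eps)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (reduction == "sum") sum(ll) else mean(ll)
}
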