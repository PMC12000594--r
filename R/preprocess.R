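#' Fit zero-mean standardization statistics on a training set
#'
#' Computes the mean and standard deviation of the raw training signals; the
#' same statistics are later applied unchanged to validation and test data so
#' that no information flows backwards from held-out trials. The default
#' `global` scope pools every sample of every channel and trial into one
#' scalar pair; `per_channel` keeps one pair per channel (pooled over trials
#' and samples). The S.D. is the population (divide-by-n) form, so
#' standardizing the training set itself yields mean 0 and S.D. 1 exactly.
#'
#' @param train a `trialset`; must be non-empty.
#' @param scope `"global"` (default) or `"per_channel"`.
#' @param eps optional non-negative ridge added to sigma; disabled (0) by
#'   default so constant signals raise an error rather than silently passing.
#' @return A `standardizer_stats` object with fields `mu`, `sigma`, `scope`.
#' @export
fit_standardizer <- function(train, scope = c("global", "per_channel"),
                             eps = 0) {
  scope <- match.arg(scope)
  if (n_trials(train) == 0L) stop("cannot fit standardizer on an empty trialset")
  x <- train$signals
  if (scope == "global") {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2)) + eps
  } else {
    n <- dim(x)[1L]; C <- dim(x)[2L]; tt <- dim(x)[3L]
    xc <- aperm(x, c(2L, 1L, 3L)); dim(xc) <- c(C, n * tt)
    mu <- rowMeans(xc)
    sigma <- sqrt(rowMeans((xc - mu)^2)) + eps
  }
  if (any(sigma <= 0))
    stop(paste0("zero standard deviation (constant signal); pass `eps` to ",
                "fit_standardizer() to regularize explicitly"))
  structure(list(mu = mu, sigma = sigma, scope = scope),
            class = "standardizer_stats")
}

#' Apply fitted standardization statistics to a trialset
#'
#' Element-wise `(x - mu) / sigma` with the train-fitted statistics; labels
#' and metadata pass through untouched.
#'
#' @param stats a `standardizer_stats` from [fit_standardizer()].
#' @param ts a `trialset`.
#' @return the standardized `trialset`.
#' @export
apply_standardizer <- function(stats, ts) {
  if (!inherits(stats, "standardizer_stats")) stop("`stats` is not fitted statistics")
  x <- ts$signals
  if (stats$scope == "global") {
    x <- (x - stats$mu) / stats$sigma
  } else {
    C <- dim(x)[2L]
    if (length(stats$mu) != C)
      stop(sprintf("per-channel stats for %d channels applied to %d channels",
                   length(stats$mu), C))
    for (c in seq_len(C))
      x[, c, ] <- (x[, c, ] - stats$mu[c]) / stats$sigma[c]
  }
  out <- ts
  out$signals <- x
  out
}
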