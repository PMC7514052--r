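#' Automatic grey-level thresholds (Huang, Yen, Otsu)
#'
#' Histogram-based automatic thresholding on a 256-bin histogram spanning
#' the image range. \code{"huang"} minimises the fuzzy Shannon entropy of
#' the two-class membership function (Huang & Wang 1995); \code{"yen"}
#' maximises Yen's maximum-correlation criterion (Yen, Chang & Chang
#' 1995); \code{"otsu"} maximises between-class variance. The returned
#' value is the centre of the selected histogram bin; pixels strictly
#' above it are foreground.
#'
#' @param img numeric matrix (or vector) of pixel intensities.
#' @param method one of "huang", "yen", "otsu".
#' @param nbins number of histogram bins.
#' @return the threshold grey level.
#' @export
autoThreshold <- function(img, method = c("huang", "yen", "otsu"),
                          nbins = 256L) {
  method <- match.arg(method)
  x <- as.numeric(img)
  if (any(!is.finite(x))) stop2("image contains non-finite pixels")
  mn <- min(x); mx <- max(x)
  if (mx == mn) return(mn)
  breaks <- seq(mn, mx, length.out = nbins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(idx, nbins)
  centers <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  switch(method,
         huang = threshold_huang(h, centers),
         yen = threshold_yen(h, centers),
         otsu = threshold_otsu(h, centers))
}

threshold_huang <- function(h, centers) {
  nb <- length(h)
  C <- centers[nb] - centers[1L]
  W <- cumsum(h * centers); N <- cumsum(h)
  Wt <- W[nb]; Nt <- N[nb]
  best <- Inf; bt <- centers[1L]
  for (t in seq_len(nb - 1L)) {
    if (N[t] == 0 || N[t] == Nt) next
    mu0 <- W[t] / N[t]
    mu1 <- (Wt - W[t]) / (Nt - N[t])
    mu <- ifelse(seq_len(nb) <= t, mu0, mu1)
    u <- 1 / (1 + abs(centers - mu) / C)
    ent <- ifelse(u > 0 & u < 1,
                  u * log(u) + (1 - u) * log(1 - u), 0)
    S <- -sum(h * ent)
    if (S < best) { best <- S; bt <- centers[t] }
  }
  bt
}

threshold_yen <- function(h, centers) {
  nb <- length(h)
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- rev(cumsum(rev(p^2)))
  t <- seq_len(nb - 1L)
  crit <- log((P1[t] * (1 - P1[t]))^2 / (P1sq[t] * P2sq[t + 1L]))
  crit[!is.finite(crit)] <- NA_real_
  centers[which.max(crit)]
}

threshold_otsu <- function(h, centers) {
  p <- h / sum(h)
  w1 <- cumsum(p)
  mu <- cumsum(p * centers)
  mut <- mu[length(mu)]
  bcv <- (mut * w1 - mu)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- NA_real_
  centers[which.max(bcv)]
}
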