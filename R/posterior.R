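#' Shortest (highest posterior density) interval of a sample
#'
#' Finds the shortest interval of consecutive order statistics containing
#' at least \code{mass} of the draws: with n draws and
#' m = ceiling(mass * n), the window \code{[x_(i), x_(i+m-1)]} of minimal
#' width over all i.
#'
#' @param x numeric vector of draws.
#' @param mass interval mass in (0, 1); default 0.95.
#' @return Numeric vector \code{c(low, high)}.
#' @export
hpdInterval <- function(x, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

# KDE mode: Gaussian kernel, Silverman bandwidth, 512-point grid on the
# draw range; grid argmax.
kdeMode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Summarize a posterior sample
#'
#' Computes a kernel-density mode, a shortest-interval HPD, and empirical
#' quantiles for a set of MCMC draws. The mode is the argmax of a Gaussian
#' KDE (Silverman bandwidth) on a 512-point grid spanning the draw range;
#' the HPD is the shortest window of consecutive sorted draws holding
#' \code{hpd_mass} of the sample; quantiles use linear interpolation of
#' order statistics (type 7).
#'
#' @param object a [PosteriorDraws-class] object or numeric vector with at
#'   least 100 draws.
#' @param hpd_mass HPD mass in (0, 1); default 0.95.
#' @param quantile_probs probabilities for the quantile table.
#' @return A [PosteriorSummary-class] object. Constant draws give a
#'   zero-width HPD at that constant.
#' @examples
#' s <- summarizePosterior(posteriorDraws(rnorm(5000), "theta"))
#' s
#' @export
setGeneric("summarizePosterior",
  function(object, hpd_mass = 0.95,
           quantile_probs = c(0.025, 0.05, 0.5, 0.95, 0.975))
    standardGeneric("summarizePosterior"))

#' @rdname summarizePosterior
#' @export
setMethod("summarizePosterior", "PosteriorDraws",
  function(object, hpd_mass = 0.95,
           quantile_probs = c(0.025, 0.05, 0.5, 0.95, 0.975)) {
    summarizePosterior(object@draws, hpd_mass, quantile_probs)
  })

#' @rdname summarizePosterior
#' @export
setMethod("summarizePosterior", "numeric",
  function(object, hpd_mass = 0.95,
           quantile_probs = c(0.025, 0.05, 0.5, 0.95, 0.975)) {
    if (length(object) < 100L)
      stop("need at least 100 draws for mode estimation")
    if (hpd_mass <= 0 || hpd_mass >= 1) stop("hpd_mass must be in (0, 1)")
    mode <- kdeMode(object)
    hpd <- hpdInterval(object, hpd_mass)
    q <- stats::quantile(object, probs = quantile_probs, type = 7,
                         names = TRUE)
    new("PosteriorSummary", mode = mode, hpd_low = hpd[1], hpd_high = hpd[2],
        hpd_mass = hpd_mass, quantiles = q,
        n_draws = length(object),
        multimodal_flag = (mode < hpd[1] || mode > hpd[2]))
  })

# summary -> plain list, for JSON reports
summaryAsList <- function(s) {
  list(mode = s@mode, hpd_low = s@hpd_low, hpd_high = s@hpd_high,
       hpd_mass = s@hpd_mass,
       quantiles = as.list(s@quantiles),
       n_draws = s@n_draws, multimodal_flag = s@multimodal_flag)
}
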