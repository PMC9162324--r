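# Distribution of fitness effects, dominance, and negative
# frequency-dependent selection used by the Wright-Fisher simulator.

#' Gamma distribution of fitness effects for deleterious mutations
#'
#' New nonsynonymous mutations draw a scaled selection strength
#' `N_e*|s|` from a gamma distribution with the given shape and mean,
#' where `N_e` is the *ancestral* effective population size. Presets carry
#' the estimates for human (`shape = 0.23`, mean `N_e*s = 425`) and
#' Drosophila melanogaster (`shape = 0.35`, mean `N_e*s = 1800`)
#' polymorphism data.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param mean_scaled_s Mean of `N_e*|s|` (>= 0).
#' @param label Free-text label.
#' @return An object of class `dfe_params`.
#' @export
dfe_params <- function(shape, mean_scaled_s, label = "custom") {
  if (shape <= 0 || mean_scaled_s < 0)
    stop("shape must be > 0 and mean_scaled_s >= 0")
  structure(list(shape = shape, mean_scaled_s = mean_scaled_s,
                 label = label), class = "dfe_params")
}

#' @rdname dfe_params
#' @export
dfe_human <- function() dfe_params(0.23, 425, "human")

#' @rdname dfe_params
#' @export
dfe_drosophila <- function() dfe_params(0.35, 1800, "drosophila")

#' Draw selection coefficients from a gamma DFE
#'
#' Returns negative selection coefficients `s` such that `n_e * |s|` is
#' gamma-distributed with the DFE's shape and mean. Values are not
#' truncated here; the simulator clamps genotype fitnesses at zero, so
#' draws with `s < -1` behave as lethals.
#'
#' @param params A [dfe_params()] object.
#' @param n Number of draws.
#' @param n_e Ancestral effective population size used to de-scale.
#' @return Numeric vector of `n` non-positive selection coefficients.
#' @export
sample_dfe <- function(params, n, n_e) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(numeric(0))
  if (params$mean_scaled_s == 0) return(numeric(n))
  -stats::rgamma(n, shape = params$shape,
                 scale = params$mean_scaled_s / params$shape) / n_e
}

#' Selection-dependent dominance model
#'
#' Dominance of a deleterious mutation decreases with the strength of
#' selection against it:
#' \deqn{h(s) = \frac{1}{1/\theta_{intercept} - \theta_{rate}\, s}, \quad s \le 0,}
#' so that neutral mutations (`s = 0`) have `h = theta_intercept` (0.5 by
#' default: codominant) and strongly deleterious mutations approach full
#' recessivity. The default rate 41225.56 is the inverse-relationship fit
#' estimated from Arabidopsis.
#'
#' @param theta_intercept Dominance at `s = 0`, in (0, 1\].
#' @param theta_rate Decay parameter (>= 0).
#' @param fixed_h Optional constant dominance overriding the model.
#' @return An object of class `dominance_model`.
#' @export
dominance_model <- function(theta_intercept = 0.5, theta_rate = 41225.56,
                            fixed_h = NULL) {
  if (theta_intercept <= 0 || theta_intercept > 1)
    stop("theta_intercept must lie in (0, 1]")
  if (theta_rate < 0) stop("theta_rate must be >= 0")
  structure(list(theta_intercept = theta_intercept, theta_rate = theta_rate,
                 fixed_h = fixed_h), class = "dominance_model")
}

#' Dominance coefficient for a given selection coefficient
#'
#' @param s Selection coefficient(s), `s <= 0` for the model branch.
#' @param model A [dominance_model()].
#' @return Dominance coefficient(s) in (0, `theta_intercept`\].
#' @examples
#' huber_dominance(0, dominance_model())       # 0.5
#' huber_dominance(-0.001, dominance_model())  # ~0.0231
#' @export
huber_dominance <- function(s, model = dominance_model()) {
  if (!is.null(model$fixed_h)) return(rep(model$fixed_h, length(s)))
  1 / (1 / model$theta_intercept - model$theta_rate * s)
}

#' Negative frequency-dependent balanced polymorphism configuration
#'
#' A balanced polymorphism is maintained by negative frequency-dependent
#' selection with a stable internal equilibrium frequency `p_eq` (drawn
#' from `eq_freq_distribution` per replicate) and a restoring force whose
#' scaled strength at the equilibrium is `scaled_ns_at_eq` (`N*s0`, with
#' `N` the ancestral population size; default 20). The polymorphism is
#' introduced `intro_time` (in units of N generations; default 5) before
#' the population split, at the centre of each exon.
#'
#' @param eq_freq_distribution Function of `n` returning `n` equilibrium
#'   frequencies in (0, 1); default `uniform(0, 1)`.
#' @param scaled_ns_at_eq Scaled strength of the restoring force (> 0).
#' @param intro_time Generations before the split, in N units (> 0).
#' @return An object of class `balanced_config`.
#' @export
balanced_config <- function(eq_freq_distribution = stats::runif,
                            scaled_ns_at_eq = 20, intro_time = 5) {
  if (scaled_ns_at_eq <= 0) stop("scaled_ns_at_eq must be > 0")
  structure(list(eq_freq_distribution = eq_freq_distribution,
                 scaled_ns_at_eq = scaled_ns_at_eq,
                 intro_time = intro_time), class = "balanced_config")
}

#' Frequency-dependent selection coefficient of the balanced allele
#'
#' The balanced allele experiences \eqn{s(p) = s_0 (1 - p/p_{eq})} with
#' \eqn{s_0 = Ns_{eq}/N}: positive selection below the equilibrium
#' frequency, zero at it, negative above it. Applied with codominance
#' (`h = 0.5`) in the simulator, this yields a restoring force of scaled
#' strength `scaled_ns_at_eq` at the equilibrium point.
#'
#' @param current_freq Current allele frequency (vectorised), in \[0,1\].
#' @param p_eq Equilibrium frequency in (0, 1).
#' @param scaled_ns_at_eq Scaled strength `N*s0` (default 20).
#' @param n Ancestral population size used to de-scale (default 200).
#' @return Effective selection coefficient(s) `s(p)`.
#' @examples
#' nfds_selection(0.5, p_eq = 0.5)  # 0 at equilibrium
#' nfds_selection(0.2, p_eq = 0.5)  # > 0: restoring
#' @export
nfds_selection <- function(current_freq, p_eq, scaled_ns_at_eq = 20,
                           n = 200) {
  if (any(current_freq < 0 | current_freq > 1))
    stop("current_freq must lie in [0, 1]")
  s0 <- scaled_ns_at_eq / n
  s0 * (1 - current_freq / p_eq)
}
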