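#' Configuration for the gel-lane simulator
#'
#' Generative model behind the closed-form cleavage estimator: the two DNA
#' strands are cut independently with probabilities `p_target` and
#' `p_nontarget`, partitioning the signal into uncut substrate, singly cut
#' (nicked) molecules and doubly cut (linearized) molecules.
#'
#' @param p_target,p_nontarget per-strand cut probabilities in `[0, 1]`.
#' @param total_signal total integrated lane intensity (> 0).
#' @param noise_sd standard deviation of Gaussian band noise (truncated at
#'   zero); 0 gives exact expected intensities.
#' @param seed master seed (see [fan_seed()]).
#' @return an object of class `gel_sim_config`.
#' @export
gel_sim_config <- function(p_target, p_nontarget, total_signal = 100,
                           noise_sd = 0, seed = 1L) {
  assert_prob(p_target)
  assert_prob(p_nontarget)
  if (!is.numeric(total_signal) || length(total_signal) != 1L ||
      total_signal <= 0) {
    stop("'total_signal' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("'noise_sd' must be a single number >= 0", call. = FALSE)
  }
  assert_count(seed, "seed", min = 0)
  structure(list(p_target = p_target, p_nontarget = p_nontarget,
                 total_signal = total_signal, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "gel_sim_config")
}

#' Simulate one gel lane under strand-independent cutting
#'
#' Band intensities: `a = total * (1 - p_t)(1 - p_nt)` (undigested),
#' `b = total * (p_t(1 - p_nt) + p_nt(1 - p_t))` (singly cut / nicked),
#' `c = total * p_t * p_nt` (doubly cut), each perturbed by Gaussian noise
#' of sd `noise_sd` truncated at 0.
#'
#' @param cfg a [gel_sim_config()].
#' @return a [gel_lane()]; the true per-strand probabilities are attached as
#'   attribute `truth`.
#' @export
#' @examples
#' simulate_gel_lanes(gel_sim_config(0.1, 0.1))
simulate_gel_lanes <- function(cfg) {
  stopifnot(inherits(cfg, "gel_sim_config"))
  pt <- cfg$p_target; pnt <- cfg$p_nontarget; tot <- cfg$total_signal
  a <- tot * (1 - pt) * (1 - pnt)
  b <- tot * (pt * (1 - pnt) + pnt * (1 - pt))
  cc <- tot * pt * pnt
  if (cfg$noise_sd > 0) {
    set.seed(fan_seed(cfg$seed, 21L))
    a <- max(0, a + rnorm(1L, sd = cfg$noise_sd))
    b <- max(0, b + rnorm(1L, sd = cfg$noise_sd))
    cc <- max(0, cc + rnorm(1L, sd = cfg$noise_sd))
  }
  lane <- gel_lane(a, b, cc)
  attr(lane, "truth") <- list(p_target = pt, p_nontarget = pnt,
                              percent_cleaved_true = 100 * pt)
  lane
}
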