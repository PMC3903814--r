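#' Single-cell sequencing error model
#'
#' The observation model linking true genotypes to called genotypes in
#' MDA-amplified single-cell sequencing. True genotypes are binary (0
#' wildtype, 1 heterozygous mutant; a true homozygous mutation at a base
#' pair is vanishingly unlikely), observed genotypes are 0/1/2. Two error
#' channels dominate:
#'
#' * **false discovery** (`fd`): a true wildtype site is called
#'   heterozygous, `Pr(obs 1 | true 0) = FD`;
#' * **allelic dropout** (`ad`): one allele of a true heterozygote fails to
#'   amplify, so the site is called homozygous either way,
#'   `Pr(obs 0 | true 1) = Pr(obs 2 | true 1) = AD / 2`.
#'
#' A residual channel `hom_fd` (`Pr(obs 2 | true 0)`) is not derivable from
#' FD and AD; it is taken as negligible (0) by default but exposed as a
#' parameter.
#'
#' Defaults are the rates measured for the Hou et al. (2012) essential
#' thrombocythemia assay: FD = 6.04e-5, AD = 0.4309.
#'
#' @param fd false discovery rate, in `[0, 1]`.
#' @param ad allelic dropout rate, in `[0, 1]`.
#' @param hom_fd residual wildtype-to-homozygous-mutant call rate;
#'   `fd + hom_fd` must not exceed 1.
#' @return An object of class `error_rates`.
#' @examples
#' e <- error_rates()
#' observation_probs(e)
#' @export
error_rates <- function(fd = 6.04e-5, ad = 0.4309, hom_fd = 0) {
  stopifnot(is.numeric(fd), is.numeric(ad), is.numeric(hom_fd),
            length(fd) == 1, length(ad) == 1, length(hom_fd) == 1)
  if (fd < 0 || fd > 1) stop("`fd` must be in [0, 1]")
  if (ad < 0 || ad > 1) stop("`ad` must be in [0, 1]")
  if (hom_fd < 0 || hom_fd > 1) stop("`hom_fd` must be in [0, 1]")
  if (fd + hom_fd > 1) stop("`fd` + `hom_fd` must not exceed 1")
  structure(list(fd = fd, ad = ad, hom_fd = hom_fd), class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat("<error_rates> FD =", format(x$fd), " AD =", format(x$ad),
      " Pr(2|0) =", format(x$hom_fd), "\n")
  invisible(x)
}

#' Single-site observation probabilities
#'
#' @param e an [error_rates()] object.
#' @return A 2 x 3 matrix `P` with `P[true + 1, obs + 1] = Pr(obs | true)`
#'   for true genotypes 0/1 and observed genotypes 0/1/2. Rows sum to 1.
#' @export
observation_probs <- function(e) {
  stopifnot(inherits(e, "error_rates"))
  matrix(c(1 - e$fd - e$hom_fd, e$fd, e$hom_fd,
           e$ad / 2, 1 - e$ad, e$ad / 2),
         nrow = 2, byrow = TRUE,
         dimnames = list(true = c("0", "1"), obs = c("0", "1", "2")))
}

#' Observation probability for a genotype pair
#'
#' Errors at the two sites of a pair are independent, so the probability of
#' an observed genotype pair given the true pair factorizes into the two
#' single-site observation probabilities.
#'
#' @param e an [error_rates()] object.
#' @param true_pair length-2 vector of true genotypes, each 0 or 1.
#' @param obs_pair length-2 vector of observed genotypes, each 0, 1 or 2.
#' @return `Pr(obs_pair | true_pair)`.
#' @examples
#' pair_observation_prob(error_rates(), c(1, 1), c(0, 0)) # (AD/2)^2
#' @export
pair_observation_prob <- function(e, true_pair, obs_pair) {
  stopifnot(length(true_pair) == 2, length(obs_pair) == 2)
  if (!all(true_pair %in% 0:1))
    stop("true genotypes must be 0 or 1, got: ",
         paste(true_pair, collapse = ", "))
  if (!all(obs_pair %in% 0:2))
    stop("observed genotypes must be 0, 1 or 2, got: ",
         paste(obs_pair, collapse = ", "))
  P <- observation_probs(e)
  P[true_pair[1] + 1L, obs_pair[1] + 1L] * P[true_pair[2] + 1L, obs_pair[2] + 1L]
}
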