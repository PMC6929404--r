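#' Simulate a set of case-control association studies with known truth
#'
#' Generates `k` studies under the random-effects data-generating model:
#' each study's true log odds ratio is drawn as
#' `theta_i ~ Normal(log(true_or), tau2)`; its control-arm effect-allele
#' frequency `p0_i ~ Uniform(p0_range)`; the case-arm frequency follows
#' from `theta_i` on the allele odds scale
#' (`logit(p1) = logit(p0) + theta`); arm sizes are uniform integers over
#' `n_range`; and per-arm genotype counts are multinomial draws under
#' Hardy-Weinberg proportions at the arm's allele frequency (optionally
#' perturbed by a disequilibrium coefficient `hwe_d`, default 0). The
#' roster row summarises its own genotype counts exactly: `maf` is the
#' combined empirical allele-C frequency and `or` the empirical allelic
#' odds ratio, so reconstruction closes the loop.
#'
#' @param k Number of studies (>= 2).
#' @param true_or True common odds ratio (default 1.12).
#' @param tau2 Between-study variance of true log odds ratios (default
#'   0.02).
#' @param n_range Integer range of per-arm sample sizes (persons), default
#'   300 to 3000.
#' @param p0_range Range of control-arm allele frequencies, default
#'   (0.2, 0.4).
#' @param hwe_d Hardy-Weinberg disequilibrium coefficient added to the
#'   homozygote class (default 0, i.e. HWE).
#' @param seed Optional integer seed; the global random state is left
#'   untouched.
#' @return A study roster tibble with genotype counts plus the per-study
#'   true log odds ratio in `true_ln_or`; the truth parameters are
#'   attached as the `"truth"` attribute.
#' @export
simulate_studies <- function(k = 37, true_or = 1.12, tau2 = 0.02,
                             n_range = c(300, 3000), p0_range = c(0.2, 0.4),
                             hwe_d = 0, seed = NULL) {
  if (k < 2 || true_or <= 0 || tau2 < 0 ||
      any(p0_range <= 0) || any(p0_range >= 1) || any(n_range < 1)) {
    abort("invalid simulation truth", class = "metasnp_validation_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  theta <- rnorm(k, log(true_or), sqrt(tau2))
  p0 <- runif(k, p0_range[1], p0_range[2])
  p1 <- plogis(qlogis(p0) + theta)
  n_case <- sample(n_range[1]:n_range[2], k, replace = TRUE)
  n_control <- sample(n_range[1]:n_range[2], k, replace = TRUE)
  geno <- function(n, p) {
    probs <- c(p^2 + hwe_d, 2 * p * (1 - p) - 2 * hwe_d, (1 - p)^2 + hwe_d)
    if (any(probs < 0)) {
      abort("hwe_d incompatible with the allele frequency",
            class = "metasnp_validation_error")
    }
    rmultinom(1, n, probs)[, 1]
  }
  g1 <- vapply(seq_len(k), function(i) geno(n_case[i], p1[i]), numeric(3))
  g0 <- vapply(seq_len(k), function(i) geno(n_control[i], p0[i]), numeric(3))
  a <- 2 * g1[1, ] + g1[2, ]
  b <- 2 * g1[3, ] + g1[2, ]
  c_ <- 2 * g0[1, ] + g0[2, ]
  d <- 2 * g0[3, ] + g0[2, ]
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  or_emp <- ifelse(zero,
                   ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)),
                   (a * d) / (b * c_))
  out <- tibble(
    label = sprintf("sim_%02d", seq_len(k)),
    group = rep(c("east_asian", "caucasian"), length.out = k),
    n_case = n_case, n_control = n_control,
    maf = (a + c_) / (2 * (n_case + n_control)),
    or = or_emp,
    cc_case = g1[1, ], ct_case = g1[2, ], tt_case = g1[3, ],
    cc_control = g0[1, ], ct_control = g0[2, ], tt_control = g0[3, ],
    true_ln_or = theta
  )
  attr(out, "truth") <- list(true_or = true_or, tau2 = tau2, k = k,
                             n_range = n_range, p0_range = p0_range,
                             hwe_d = hwe_d, seed = seed)
  out
}

#' Simulate a homogeneous null study set
#'
#' A study roster with no effect (`true_or = 1`) and no between-study
#' heterogeneity (`tau2 = 0`): the unbiased, symmetric funnel used to
#' check the type-I behaviour of the Q, Begg and Egger tests.
#'
#' @inheritParams simulate_studies
#' @return As [simulate_studies()].
#' @export
simulate_null_funnel <- function(k = 20, n_range = c(300, 3000),
                                 p0_range = c(0.2, 0.4), seed = NULL) {
  simulate_studies(k = k, true_or = 1, tau2 = 0, n_range = n_range,
                   p0_range = p0_range, seed = seed)
}
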