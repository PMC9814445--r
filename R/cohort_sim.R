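## Synthetic three-class plasma cohort (normal / liver disease / HCC) at the
## marker level, under the standard ctDNA dilution assumption: an HCC
## sample's true marker beta is a mixture
##     beta = (1 - theta) * beta_background + theta * beta_tumor
## with tumor fraction theta depending on stage. Observed betas are
## beta-binomial counts at fixed sequencing depth. Stage tumor-fraction
## ranges, the liver-disease background shift, and the serology models are
## implementer-chosen plausible values, not taken from any publication.

#' Cohort simulation parameters
#'
#' Defaults mirror the clinical split of the screening study the package is
#' patterned on: training 195 normal / 54 liver disease / 168 HCC, test
#' 84 / 22 / 73, and 283 panel markers at ~800x unique depth.
#'
#' @param n_train,n_test named integer vectors (`normal`, `liver`, `hcc`).
#' @param n_markers number of panel markers M.
#' @param bg_range range of per-marker background (non-tumor plasma) mean
#'   beta; marker means are drawn uniformly within it.
#' @param tumor_range range of per-marker tumor beta.
#' @param liver_shift additive background shift in liver-disease samples on
#'   the affected marker subset.
#' @param liver_frac fraction of markers affected by `liver_shift`.
#' @param stage_theta named list of tumor-fraction ranges per stage
#'   (`I`, `II`, `III-IV`).
#' @param stage_probs stage mixture among HCC samples.
#' @param depth sequencing depth per marker (reads contributing to a beta).
#' @param overdispersion beta-binomial overdispersion rho in (0, 1); 0 gives
#'   pure binomial sampling.
#' @param afp_cutoff,pivka_cutoff serology positivity cutoffs (ng/mL).
#' @param seed integer seed.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n_train = c(normal = 195, liver = 54, hcc = 168),
                          n_test = c(normal = 84, liver = 22, hcc = 73),
                          n_markers = 283,
                          bg_range = c(0.02, 0.12),
                          tumor_range = c(0.55, 0.90),
                          liver_shift = 0.05, liver_frac = 0.2,
                          stage_theta = list(
                            "I" = c(0.005, 0.03),
                            "II" = c(0.01, 0.06),
                            "III-IV" = c(0.03, 0.20)),
                          stage_probs = c(0.55, 0.13, 0.32),
                          depth = 800, overdispersion = 0.005,
                          afp_cutoff = 20, pivka_cutoff = 40,
                          seed = NULL) {
  check_count(n_markers, "n_markers", 1L)
  check_count(depth, "depth", 1L)
  stopifnot(all(n_train >= 0), all(n_test >= 0),
            all(unlist(stage_theta) >= 0), all(unlist(stage_theta) <= 1),
            overdispersion >= 0, overdispersion < 1,
            length(stage_probs) == length(stage_theta))
  structure(list(n_train = n_train, n_test = n_test,
                 n_markers = as.integer(n_markers),
                 bg_range = bg_range, tumor_range = tumor_range,
                 liver_shift = liver_shift, liver_frac = liver_frac,
                 stage_theta = stage_theta,
                 stage_probs = stage_probs / sum(stage_probs),
                 depth = as.integer(depth),
                 overdispersion = overdispersion,
                 afp_cutoff = afp_cutoff, pivka_cutoff = pivka_cutoff,
                 seed = seed), class = "cohort_params")
}

## Beta-binomial beta draw around mean mu at given depth/overdispersion.
rbetabinom_beta <- function(mu, depth, rho) {
  mu <- pmin(pmax(mu, 0), 1)
  p <- mu
  if (rho > 0) {
    nu <- (1 - rho) / rho
    ok <- mu > 0 & mu < 1
    p[ok] <- rbeta(sum(ok), mu[ok] * nu, (1 - mu[ok]) * nu)
  }
  rbinom(length(mu), depth, p) / depth
}

#' Simulate a plasma cohort
#'
#' @param params a [cohort_params()].
#' @param seed seed overriding `params$seed`.
#' @param noiseless if `TRUE`, observed betas equal the true mixture betas
#'   (an infinite-depth proxy; no sampling noise).
#' @return a `cohort` object: list with `samples` (data.frame: `id`, `class`,
#'   `stage`, `theta`, `afp`, `pivka`, `split`) and `beta` (markers x samples
#'   matrix, columns named by sample id), plus `params`.
#' @export
simulate_cohort <- function(params = cohort_params(), seed = NULL,
                            noiseless = FALSE) {
  if (is.null(seed)) seed <- if (is.null(params$seed)) 1L else params$seed
  with_seed(seed, {
    M <- params$n_markers
    mu_bg <- runif(M, params$bg_range[1], params$bg_range[2])
    mu_tum <- runif(M, params$tumor_range[1], params$tumor_range[2])
    liver_markers <- which(runif(M) < params$liver_frac)

    mk <- function(class, n, split) {
      if (n == 0L) return(NULL)
      data.frame(class = rep(class, n), split = rep(split, n))
    }
    samples <- rbind(
      mk("normal", params$n_train[["normal"]], "train"),
      mk("liver", params$n_train[["liver"]], "train"),
      mk("hcc", params$n_train[["hcc"]], "train"),
      mk("normal", params$n_test[["normal"]], "test"),
      mk("liver", params$n_test[["liver"]], "test"),
      mk("hcc", params$n_test[["hcc"]], "test"))
    n <- nrow(samples)
    samples$id <- sprintf("S%04d", seq_len(n))
    stages <- names(params$stage_theta)
    samples$stage <- NA_character_
    is_hcc <- samples$class == "hcc"
    samples$stage[is_hcc] <- sample(stages, sum(is_hcc), replace = TRUE,
                                    prob = params$stage_probs)
    samples$theta <- 0
    for (s in stages) {
      idx <- which(is_hcc & samples$stage == s)
      rng <- params$stage_theta[[s]]
      samples$theta[idx] <- runif(length(idx), rng[1], rng[2])
    }

    beta <- matrix(NA_real_, M, n,
                   dimnames = list(sprintf("marker_%03d", seq_len(M)),
                                   samples$id))
    for (j in seq_len(n)) {
      mu <- mu_bg
      if (samples$class[j] == "liver" && length(liver_markers))
        mu[liver_markers] <- pmin(mu[liver_markers] + params$liver_shift, 1)
      th <- samples$theta[j]
      mu <- (1 - th) * mu + th * mu_tum
      beta[, j] <- if (noiseless) mu else
        rbetabinom_beta(mu, params$depth, params$overdispersion)
    }

    ## Serology: lognormal with class- and tumor-fraction-dependent mean,
    ## so low-burden HCC samples can be AFP/PIVKA negative.
    samples$afp <- NA_real_
    samples$pivka <- NA_real_
    for (j in seq_len(n)) {
      th <- samples$theta[j]
      samples$afp[j] <- switch(samples$class[j],
        normal = rlnorm(1, log(4), 0.6),
        liver = rlnorm(1, log(8), 0.8),
        hcc = rlnorm(1, log(8) + 40 * th, 1.0))
      samples$pivka[j] <- switch(samples$class[j],
        normal = rlnorm(1, log(15), 0.5),
        liver = rlnorm(1, log(25), 0.7),
        hcc = rlnorm(1, log(25) + 45 * th, 1.0))
    }
    samples <- samples[, c("id", "class", "stage", "theta", "afp", "pivka",
                           "split")]
    structure(list(samples = samples, beta = beta, params = params,
                   truth = list(mu_bg = mu_bg, mu_tum = mu_tum,
                                liver_markers = liver_markers)),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$samples$class, x$samples$split)
  cat(sprintf("cohort: %d samples x %d markers\n", nrow(x$samples),
              nrow(x$beta)))
  print(tab)
  invisible(x)
}
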