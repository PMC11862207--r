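# Negative-binomial mixed models of per-mountain alien richness:
# collinearity screening, standardization, the NB GLMM with nested random
# intercepts and a log-area offset, taxon-specific refits, and sensitivity
# refits over mountain subsets.

#' Iterative collinearity screen
#'
#' Removes numeric predictors until no pair has |Pearson r| above the
#' threshold; at each step the predictor with the largest mean absolute
#' correlation to all remaining others is dropped (ties broken by column
#' order). Categorical columns are exempt and passed through.
#'
#' @param predictors data.frame of candidate predictors.
#' @param threshold absolute correlation above which a pair is collinear.
#' @return list: `retained`, `removed` (in removal order), and `correlations`
#'   (the full initial matrix, pairwise-complete).
#' @export
collinearity_screen <- function(predictors, threshold = 0.7) {
  num <- names(predictors)[vapply(predictors, is.numeric, TRUE)]
  if (nrow(predictors) < 2) stop_oro("need >= 2 rows")
  if (length(num) < 2)
    return(list(retained = names(predictors), removed = character(0),
                correlations = NULL))
  cm0 <- cor(predictors[num], use = "pairwise.complete.obs")
  keep <- num
  removed <- character(0)
  repeat {
    cm <- cm0[keep, keep, drop = FALSE]
    diag(cm) <- 0
    if (all(abs(cm) <= threshold, na.rm = TRUE)) break
    worst <- which.max(rowMeans(abs(cm), na.rm = TRUE))  # first wins ties
    removed <- c(removed, keep[worst])
    keep <- keep[-worst]
  }
  list(retained = c(keep, setdiff(names(predictors), num)),
       removed = removed, correlations = cm0)
}

#' Standardize predictors to mean 0, SD 1
#'
#' Uses the sample SD. Scaling constants are attached for back-transforming
#' coefficients to raw-unit effects.
#'
#' @param predictors data.frame; all numeric columns are scaled.
#' @return list: `data` (scaled), `center`, `scale` (named vectors).
#' @export
standardize <- function(predictors) {
  num <- names(predictors)[vapply(predictors, is.numeric, TRUE)]
  ctr <- vapply(predictors[num], mean, 0, na.rm = TRUE)
  scl <- vapply(predictors[num], sd, 0, na.rm = TRUE)
  zero <- num[scl == 0 | is.na(scl)]
  if (length(zero))
    stop_oro("zero-SD column(s): ", paste(zero, collapse = ", "))
  out <- predictors
  for (v in num) out[[v]] <- (out[[v]] - ctr[[v]]) / scl[[v]]
  list(data = out, center = ctr, scale = scl)
}

#' Invert [standardize]
#'
#' @param std a [standardize] result.
#' @return the original data.frame (within floating-point error).
#' @export
unstandardize <- function(std) {
  out <- std$data
  for (v in names(std$center))
    out[[v]] <- out[[v]] * std$scale[[v]] + std$center[[v]]
  out
}

nested_re_terms <- function(random) {
  # explicit nesting: continent, continent:region, continent:region:system
  labs <- Reduce(function(a, b) paste(a, b, sep = ":"), random,
                 accumulate = TRUE)
  paste(sprintf("(1 | %s)", labs), collapse = " + ")
}

#' Fit a negative-binomial GLMM of alien richness
#'
#' NB2 with log link, fixed effects for the (already standardized)
#' predictors, `log(area)` as an offset, and Gaussian nested random
#' intercepts (system in region in continent). The categorical `geometry`
#' predictor uses `diamond` as the reference level. Estimation profiles the
#' NB dispersion: glmer fits with a fixed-theta NB family alternate with ML
#' updates of theta until convergence (`method = "profile"`, the default;
#' `nagq = 0` uses the fast penalized-likelihood step for the fixed effects,
#' `nagq = 1` the full Laplace approximation). `method = "glmer.nb"`
#' delegates to [lme4::glmer.nb] (slow, reference route).
#'
#' @param data data.frame with the response, predictors, `area_km2`, and
#'   hierarchy columns. Incomplete rows are dropped and counted.
#' @param predictors character vector of fixed-effect columns.
#' @param response name of the count column.
#' @param random hierarchy columns, outermost first.
#' @param method `"profile"` or `"glmer.nb"`.
#' @param nagq integer, see above.
#' @param max_iter maximum theta-profile iterations.
#' @return an object of class `ovd_glmm`: `coefficients` (term, estimate, se,
#'   z, p), `theta`, `ranef_sd`, `n`, `n_dropped`, `converged`, `singular`,
#'   `loglik_trace`, and the underlying `model`.
#' @export
fit_nb_glmm <- function(data, predictors,
                        response = "n_species",
                        random = c("continent_id", "region_id", "system_id"),
                        method = c("profile", "glmer.nb"),
                        nagq = 0, max_iter = 10) {
  method <- match.arg(method)
  need <- c(response, predictors, "area_km2", random)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_oro("missing column(s): ", paste(miss, collapse = ", "))
  cc <- complete.cases(data[need])
  n_dropped <- sum(!cc)
  d <- data[cc, , drop = FALSE]
  if ("geometry" %in% predictors)
    d$geometry <- stats::relevel(factor(d$geometry,
                                        levels = GEOMETRY_CLASSES), "diamond")
  for (g in random) {
    d[[g]] <- factor(d[[g]])
    if (nlevels(d[[g]]) < 5)
      warn_oro("random level ", g, " has ", nlevels(d[[g]]),
               " groups (< 5); its variance is weakly identified")
  }
  fml <- as.formula(paste(
    response, "~", paste(predictors, collapse = " + "), "+",
    nested_re_terms(random), "+ offset(log(area_km2))"))
  ctrl <- lme4::glmerControl(calc.derivs = FALSE,
                             check.conv.grad = "ignore",
                             check.conv.singular = "ignore",
                             check.conv.hess = "ignore")
  loglik_trace <- numeric(0)
  if (method == "glmer.nb") {
    model <- lme4::glmer.nb(fml, data = d)
    theta <- lme4::getME(model, "glmer.nb.theta")
    converged <- length(model@optinfo$conv$lme4) == 0
  } else {
    model <- suppressWarnings(
      lme4::glmer(fml, data = d, family = stats::poisson, nAGQ = nagq,
                  control = ctrl))
    theta <- NA_real_
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      th_new <- suppressWarnings(
        as.vector(MASS::theta.ml(d[[response]], fitted(model), limit = 50)))
      th_new <- min(max(th_new, 1e-3), 1e6)  # keep the NB family numeric
      st <- if (nagq == 0) list(theta = lme4::getME(model, "theta"))
            else list(theta = lme4::getME(model, "theta"),
                      fixef = lme4::fixef(model))
      fam <- MASS::negative.binomial(theta = th_new)
      m_new <- tryCatch(
        suppressWarnings(update(model, family = fam, start = st)),
        error = function(e) tryCatch(          # cold restart
          suppressWarnings(update(model, family = fam, start = NULL)),
          error = function(e2) NULL))
      if (is.null(m_new)) {
        if (is.na(theta))
          stop_oro("NB GLMM failed to fit (inner PIRLS did not converge)")
        break  # keep the last successful fit, flagged below
      }
      model <- m_new
      loglik_trace <- c(loglik_trace, as.numeric(stats::logLik(model)))
      if (!is.na(theta) && abs(log(th_new) - log(theta)) < 1e-3) {
        theta <- th_new; converged <- TRUE; break
      }
      theta <- th_new
    }
  }
  smr <- summary(model)$coefficients
  coefs <- data.frame(term = rownames(smr), estimate = smr[, 1],
                      se = smr[, 2], z = smr[, 3],
                      p = 2 * pnorm(-abs(smr[, 3])),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  vc <- lme4::VarCorr(model)
  ranef_sd <- vapply(vc, function(v) sqrt(v[1]), 0)
  singular <- any(ranef_sd < 1e-6)
  if (!converged)
    warn_oro("NB GLMM flagged as not converged (theta profile did not ",
             "stabilise in ", max_iter, " iterations)")
  structure(list(coefficients = coefs, theta = theta, ranef_sd = ranef_sd,
                 n = nrow(d), n_dropped = n_dropped, converged = converged,
                 singular = singular, loglik_trace = loglik_trace,
                 formula = fml, model = model,
                 note = paste("Wald z statistics reported; the nonstandard",
                              "F statistics sometimes quoted for mixed NB",
                              "models are not reproduced")),
            class = "ovd_glmm")
}

#' @export
print.ovd_glmm <- function(x, ...) {
  cat(sprintf("<NB GLMM: n = %d (%d dropped), theta = %.3f%s%s>\n",
              x$n, x$n_dropped, x$theta,
              if (x$singular) ", singular RE fit" else "",
              if (!x$converged) ", NOT CONVERGED" else ""))
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), z = round(z, 3),
                  p = signif(p, 3)), row.names = FALSE)
  cat("random-intercept SDs:",
      paste(sprintf("%s = %.3f", names(x$ranef_sd), x$ranef_sd),
            collapse = ", "), "\n")
  invisible(x)
}

#' Taxon-specific NB GLMMs
#'
#' Refits the model spec on the mountains having at least one alien species
#' of each class, restandardizing the numeric predictors within each subset.
#' Subsets smaller than `10 x` the number of fixed-effect columns are refused
#' (`NULL` with a diagnostic attribute).
#'
#' @param data cross-taxon model table (raw, unstandardized predictors).
#' @param richness long table from [richness_table] (gives the per-class
#'   mountain subsets).
#' @param predictors fixed-effect columns.
#' @param classes taxon classes to fit.
#' @param ... passed to [fit_nb_glmm].
#' @return named list of `ovd_glmm` (or `NULL` where refused); per-class
#'   counts in attribute `"subset_sizes"`.
#' @export
taxon_models <- function(data, richness, predictors,
                         classes = TAXON_CLASSES, ...) {
  out <- setNames(vector("list", length(classes)), classes)
  sizes <- setNames(integer(length(classes)), classes)
  num <- intersect(predictors,
                   names(data)[vapply(data, is.numeric, TRUE)])
  for (cl in classes) {
    sub_r <- richness[richness$scope == cl & richness$n_species >= 1, ]
    d <- data[data$mountain_id %in% sub_r$mountain_id, , drop = FALSE]
    # per-class response: alien species of that class
    d$n_species <- sub_r$n_species[match(d$mountain_id, sub_r$mountain_id)]
    sizes[cl] <- nrow(d)
    if (nrow(d) < 10 * length(predictors)) {
      attr(out, "refused") <- c(attr(out, "refused"),
                                setNames(nrow(d), cl))
      next
    }
    std <- standardize(d[num])
    d[num] <- std$data
    out[[cl]] <- fit_nb_glmm(d, predictors, ...)
  }
  attr(out, "subset_sizes") <- sizes
  out
}

#' Sensitivity refits over mountain subsets
#'
#' Refits the model over a list of row subsets (defaults: 20 random 80%
#' draws plus drop-one-continent) and reports, per coefficient, the fraction
#' of successful refits preserving the full-fit sign and the fraction
#' significant at p < 0.05. Failed refits are recorded, not dropped.
#'
#' @param data standardized model table.
#' @param predictors fixed-effect columns.
#' @param rules optional named list of integer row-index vectors; defaults
#'   are built from `seed`.
#' @param n_random number of random 80% subsets when `rules` is NULL.
#' @param seed integer seed for the random subsets.
#' @param ... passed to [fit_nb_glmm].
#' @return data.frame: term, sign_stability, sig_fraction, n_ok, n_failed;
#'   the full fit rides along as attribute `"full_fit"`.
#' @export
sensitivity_refits <- function(data, predictors, rules = NULL,
                               n_random = 20, seed = 1L, ...) {
  full <- fit_nb_glmm(data, predictors, ...)
  if (is.null(rules)) {
    set.seed(seed)
    rules <- list()
    for (b in seq_len(n_random))
      rules[[sprintf("random80_%02d", b)]] <-
        sort(sample.int(nrow(data), round(0.8 * nrow(data))))
    for (cc in unique(data$continent_id))
      rules[[paste0("drop_", cc)]] <- which(data$continent_id != cc)
  }
  if (length(rules) < 2) stop_oro("need >= 2 subset rules")
  terms <- full$coefficients$term
  sgn <- sign(full$coefficients$estimate)
  hits <- matrix(NA, length(rules), length(terms),
                 dimnames = list(names(rules), terms))
  sig <- hits
  failed <- character(0)
  for (rn in names(rules)) {
    f <- try(suppressWarnings(
      fit_nb_glmm(data[rules[[rn]], , drop = FALSE], predictors, ...)),
      silent = TRUE)
    if (inherits(f, "try-error")) { failed <- c(failed, rn); next }
    m <- match(terms, f$coefficients$term)
    hits[rn, ] <- sign(f$coefficients$estimate[m]) == sgn
    sig[rn, ] <- f$coefficients$p[m] < 0.05
  }
  out <- data.frame(
    term = terms,
    sign_stability = colMeans(hits, na.rm = TRUE),
    sig_fraction = colMeans(sig, na.rm = TRUE),
    n_ok = colSums(!is.na(hits)),
    n_failed = length(failed),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "full_fit") <- full
  attr(out, "failed_rules") <- failed
  out
}
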