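# Lasso-penalized Cox selection of TcEMMs with clinical covariates left
# unpenalized, 10-fold cross-validated penalty choice, a KKT check on the
# fitted solution, and sample-splitting post-selection inference.

# Gradient of the Cox log partial likelihood (Breslow ties), used for the
# KKT verification of penalized fits. Written independently of glmnet.
cox_breslow_gradient <- function(beta, time, event, X) {
  eta <- as.numeric(X %*% beta)
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)  # descending: cumsum = risk sets
  t_o <- time[ord]; e_o <- event[ord]; w_o <- w[ord]
  X_o <- X[ord, , drop = FALSE]
  S0 <- cumsum(w_o)
  S1 <- apply(X_o * w_o, 2L, cumsum)
  # ties: risk set at an event time includes everyone with time >= t
  last_at_value <- cumsum(as.numeric(table(factor(t_o, levels = unique(t_o)))))
  idx_full <- rep(last_at_value, diff(c(0, last_at_value)))
  S0_full <- S0[idx_full]
  S1_full <- S1[idx_full, , drop = FALSE]
  ev <- which(e_o == 1)
  colSums(X_o[ev, , drop = FALSE] - S1_full[ev, , drop = FALSE] / S0_full[ev])
}

#' KKT check of a penalized Cox solution
#'
#' Verifies the stationarity conditions of the elastic-net Cox objective at
#' a fitted coefficient vector: for penalized coefficients,
#' `|grad_j| <= lambda` when `beta_j = 0` and `grad_j = lambda * sign(beta_j)`
#' otherwise; unpenalized gradients must vanish. Gradients are of the
#' per-observation-scaled log partial likelihood, matching the glmnet Cox
#' objective.
#'
#' @param beta named coefficient vector (all design columns).
#' @param time,event survival outcome.
#' @param design numeric design matrix.
#' @param penalized logical vector over design columns.
#' @param lambda penalty value (on glmnet's scale; per-column penalties are
#'   rescaled internally as glmnet does, i.e. penalty factors are
#'   renormalized to sum to the number of columns).
#' @param tol tolerance on the conditions.
#' @return list with `ok` (logical) and `max_violation`.
#' @export
kkt_check <- function(beta, time, event, design, penalized, lambda,
                      tol = 1e-4) {
  n <- length(time)
  g <- cox_breslow_gradient(beta, time, event, design) / n
  lam_j <- lambda * as.numeric(penalized) *
    length(penalized) / sum(penalized)
  viol <- numeric(length(beta))
  for (j in seq_along(beta)) {
    if (!penalized[j]) {
      viol[j] <- abs(g[j])
    } else if (abs(beta[j]) > 1e-12) {
      viol[j] <- abs(g[j] - lam_j[j] * sign(beta[j]))
    } else {
      viol[j] <- max(0, abs(g[j]) - lam_j[j])
    }
  }
  list(ok = max(viol) <= tol, max_violation = max(viol))
}

#' Fit a Cox Lasso at a fixed penalty
#'
#' L1-penalized Cox regression via [glmnet::glmnet()] with TcEMM columns
#' penalized and clinical/DRB1 columns unpenalized. Binary TcEMM columns
#' are not standardized (equal penalty per mismatch); continuous clinical
#' covariates are expected already centered/scaled. Ties are handled by the
#' Breslow approximation (glmnet's convention).
#'
#' @param time,event survival outcome.
#' @param design numeric design matrix.
#' @param penalized logical vector: which columns carry the L1 penalty.
#' @param lambda single penalty value (0 allowed).
#' @return named coefficient vector over the design columns.
#' @export
fit_cox_lasso <- function(time, event, design, penalized, lambda) {
  y <- survival::Surv(time, event)
  pf <- as.numeric(penalized)
  base <- glmnet::glmnet(design, y, family = "cox", penalty.factor = pf,
                         standardize = FALSE, nlambda = 50)
  lam_seq <- sort(unique(c(base$lambda[base$lambda > lambda], lambda)),
                  decreasing = TRUE)
  fit <- glmnet::glmnet(design, y, family = "cox", penalty.factor = pf,
                        standardize = FALSE, lambda = lam_seq,
                        thresh = 1e-12)
  cf <- as.numeric(coef(fit, s = lambda, exact = FALSE))
  setNames(cf, colnames(design))
}

# Event-stratified fold assignment, deterministic given seed
stratified_folds <- function(event, n_folds, seed) {
  withr::with_seed(seed, {
    foldid <- integer(length(event))
    for (grp in list(which(event == 1), which(event == 0))) {
      if (length(grp) > 0) {
        foldid[grp] <- sample(rep_len(seq_len(n_folds), length(grp)))
      }
    }
    foldid
  })
}

#' Cross-validated Lasso penalty selection
#'
#' Runs `n_folds`-fold cross-validation of the penalized Cox model over a
#' grid of 100 log-spaced penalties from the smallest all-zero penalty down
#' to 1% of it, minimizing partial-likelihood deviance. Folds are
#' event-stratified and deterministic given `seed`.
#'
#' @inheritParams fit_cox_lasso
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param nlambda grid length.
#' @param lambda_min_ratio smallest penalty as a fraction of the maximum.
#' @return A `lasso_path` list: `lambdas`, `n_nonzero` (penalized nonzeros
#'   per penalty), `cv_mean`, `cv_se`, `lambda_min`, `selected` (penalized
#'   columns nonzero at `lambda_min`), `coefficients` (at `lambda_min`),
#'   and the underlying `cv.glmnet` fit.
#' @export
cv_select_lambda <- function(time, event, design, penalized,
                             n_folds = 10L, seed = 1L, nlambda = 100L,
                             lambda_min_ratio = 0.01) {
  stopifnot(n_folds >= 2)
  if (sum(event) < n_folds) {
    stop("need at least one event per fold (", sum(event), " events for ",
         n_folds, " folds)", call. = FALSE)
  }
  foldid <- stratified_folds(event, n_folds, seed)
  y <- survival::Surv(time, event)
  pf <- as.numeric(penalized)
  cvfit <- glmnet::cv.glmnet(design, y, family = "cox", foldid = foldid,
                             penalty.factor = pf, standardize = FALSE,
                             nlambda = nlambda,
                             lambda.min.ratio = lambda_min_ratio,
                             type.measure = "deviance")
  cf <- as.numeric(coef(cvfit, s = "lambda.min"))
  names(cf) <- colnames(design)
  nz <- apply(as.matrix(coef(cvfit$glmnet.fit)), 2L, function(b) {
    sum(abs(b[penalized]) > 0)
  })
  structure(list(lambdas = cvfit$lambda,
                 n_nonzero = unname(nz),
                 cv_mean = cvfit$cvm,
                 cv_se = cvfit$cvsd,
                 lambda_min = cvfit$lambda.min,
                 selected = colnames(design)[penalized & abs(cf) > 0],
                 coefficients = cf,
                 foldid = foldid,
                 cvfit = cvfit),
            class = "lasso_path")
}

# Unpenalized Cox refit of selected TcEMMs + all unpenalized covariates;
# Wald HRs/CIs per selected column.
cox_refit <- function(time, event, design, columns) {
  dat <- list(y = survival::Surv(time, event),
              X = design[, columns, drop = FALSE])
  fit <- survival::coxph(y ~ X, data = dat, ties = "breslow")
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  names(cf) <- names(se) <- colnames(dat$X)  # coxph keeps column order
  z <- qnorm(0.975)
  data.frame(term = names(cf),
             hr = exp(cf),
             ci_lo = exp(cf - z * se),
             ci_hi = exp(cf + z * se),
             p = 2 * pnorm(-abs(cf / se)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Post-selection inference for Lasso-selected TcEMMs
#'
#' Default method `"split"`: the data are split in half (event-stratified);
#' Lasso selection (or the supplied `selection`) determines the model on
#' one half, and an unpenalized Cox model with the selected TcEMMs plus all
#' unpenalized covariates is fit on the held-out half, yielding valid Wald
#' 95% confidence intervals. A TcEMM is significant iff its CI excludes
#' HR = 1. Method `"naive"` refits on the full data and is reported with a
#' validity warning.
#'
#' @inheritParams cv_select_lambda
#' @param selection optional character vector of TcEMM columns to treat as
#'   selected. If `NULL` (default) and `method = "split"`, selection is
#'   re-run by cross-validated Lasso on the selection half.
#' @param method `"split"` or `"naive"`.
#' @param class_origin optional named vector mapping TcEMM columns to HLA
#'   class of origin (`"I"`, `"II"`, `"I+II"`) for the summary counts.
#' @return A `selection_result` list: `selected`, `posi_significant`,
#'   `table` (per-TcEMM refit HR, CI, p, significance), `class_counts`
#'   (selected and significant counts by class) and `method`.
#' @export
posi_inference <- function(time, event, design, penalized,
                           selection = NULL, method = c("split", "naive"),
                           seed = 1L, n_folds = 10L, class_origin = NULL) {
  method <- match.arg(method)
  unpen_cols <- colnames(design)[!penalized]
  if (method == "naive") {
    warning("naive post-selection inference refits on the full data; ",
            "intervals do not account for selection")
    if (is.null(selection)) {
      stop("method = 'naive' requires an explicit selection", call. = FALSE)
    }
    selected <- selection
    fit_idx <- seq_along(time)
  } else {
    halves <- stratified_folds(event, 2L, seed)
    if (is.null(selection)) {
      sel_idx <- which(halves == 1L)
      path <- cv_select_lambda(time[sel_idx], event[sel_idx],
                               design[sel_idx, , drop = FALSE], penalized,
                               n_folds = n_folds,
                               seed = derive_seeds(seed, 1L, salt = 11L))
      selected <- path$selected
    } else {
      selected <- selection
    }
    fit_idx <- which(halves == 2L)
  }
  empty <- list(selected = selected, posi_significant = character(0),
                table = data.frame(), method = method,
                class_counts = count_by_class(character(0), character(0),
                                              class_origin))
  if (length(selected) == 0) {
    empty$table <- data.frame(term = character(0))
    class(empty) <- "selection_result"
    return(empty)
  }
  n_events_fit <- sum(event[fit_idx])
  if (length(selected) > n_events_fit / 10) {
    warning("selected set (", length(selected), ") is large relative to ",
            n_events_fit, " held-out events; refit may be unstable")
  }
  tab <- cox_refit(time[fit_idx], event[fit_idx],
                   design[fit_idx, , drop = FALSE],
                   c(selected, unpen_cols))
  tab <- tab[tab$term %in% selected, , drop = FALSE]
  tab$significant <- tab$ci_lo > 1 | tab$ci_hi < 1
  sig <- tab$term[tab$significant]
  structure(list(selected = selected,
                 posi_significant = sig,
                 table = tab,
                 method = method,
                 class_counts = count_by_class(selected, sig, class_origin)),
            class = "selection_result")
}

# Counts by HLA class of origin; cores found in both classes count toward
# both (the registry-scale reports tally classes separately).
count_by_class <- function(selected, significant, class_origin) {
  if (is.null(class_origin)) return(NULL)
  is1 <- function(ids) sum(class_origin[ids] %in% c("I", "I+II"))
  is2 <- function(ids) sum(class_origin[ids] %in% c("II", "I+II"))
  list(n_selected_classI = is1(selected),
       n_selected_classII = is2(selected),
       n_significant_classI = is1(significant),
       n_significant_classII = is2(significant))
}
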