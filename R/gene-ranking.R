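RANKING_FEATURES <- c("subgraph_centrality", "closeness", "degree_total",
                      "pagerank", "eigenvector")

#' Build a standardized centrality feature table for gene ranking
#'
#' Collects the five centrality features (subgraph centrality, closeness,
#' total degree, PageRank, eigenvector centrality) for every gene of a
#' subnetwork and attaches the binary outcome label.  Features are
#' standardized to mean 0 / SD 1; constant features carry no information for
#' the fit and are dropped with a warning.
#'
#' @param subnet An `igraph` subnetwork.
#' @param measures Optional precomputed [centrality_features()] table.
#' @param catalog A [gene_catalog()] (required for `label = "radiation"`).
#' @param label `"radiation"` (default: catalog membership) or `"set"`
#'   (membership of `set_members`).
#' @param set_members Gene IDs defining the positive class when
#'   `label = "set"`.
#' @return Object of class `"feature_table"`: data.frame of standardized
#'   features with `gene` and logical `label` columns; raw features kept in
#'   the `"raw"` attribute.
#' @export
build_features <- function(subnet, measures = NULL, catalog = NULL,
                           label = c("radiation", "set"), set_members = NULL) {
  label <- match.arg(label)
  measures <- measures %||% centrality_features(subnet)
  genes <- igraph::V(subnet)$name
  if (!all(genes %in% measures$gene))
    stop("measures must cover every subnetwork gene")
  measures <- measures[match(genes, measures$gene), , drop = FALSE]
  y <- switch(label,
              radiation = {
                if (is.null(catalog)) stop("label = 'radiation' needs a gene catalog")
                genes %in% catalog$radiation_induced
              },
              set = {
                if (is.null(set_members)) stop("label = 'set' needs set_members")
                genes %in% toupper(set_members)
              })
  if (length(unique(y)) < 2L)
    stop("all genes fall in one class under label '", label,
         "'; choose another label")
  X <- as.matrix(measures[, RANKING_FEATURES, drop = FALSE])
  keep <- apply(X, 2L, sd) > 0
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no informative features left")
  Xs <- scale(X)
  out <- data.frame(gene = genes, Xs, label = y, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "raw") <- X
  class(out) <- c("feature_table", "data.frame")
  out
}

# Ridge-penalized IRLS fallback for separated fits (penalty excluded from the
# intercept).  Returns coefficients and the penalized-information covariance.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 200, tol = 1e-8) {
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(Xd))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    H <- crossprod(Xd, Xd * W) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  vcv <- solve(H)
  list(coefficients = setNames(as.numeric(beta), colnames(Xd)), vcov = vcv,
       fitted = 1 / (1 + exp(-as.numeric(Xd %*% beta))), iter = i)
}

#' Fit the gene-category logistic regression
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of the binary gene label on the standardized centrality features,
#' reporting coefficients, Wald p-values and odds ratios.  Perfect or
#' quasi-perfect separation -- common when hubs split cleanly from leaves --
#' is detected and handled by refitting with a small L2 ridge (1e-4), noted
#' on the returned model.
#'
#' @param features A [build_features()] table.
#' @param max_iter IRLS iteration cap (default 100).
#' @param tol Convergence tolerance on coefficient change (default 1e-8).
#' @return Object of class `"gene_logit"`: coefficients, `se`, `p_value`,
#'   `odds_ratio`, `fitted` probabilities, `separation` flag and feature
#'   names.
#' @export
fit_logistic <- function(features, max_iter = 100, tol = 1e-8) {
  stopifnot(inherits(features, "feature_table"))
  feats <- setdiff(colnames(features), c("gene", "label"))
  X <- as.matrix(features[, feats, drop = FALSE])
  y <- as.numeric(features$label)
  if (nrow(X) <= ncol(X)) stop("need more genes than features")

  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ X, family = binomial(),
        control = glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged && !separated)
    stop("IRLS did not converge in ", max_iter,
         " iterations (deviance ", format(fit$deviance), ")")
  cf <- coef(fit)
  if (separated || !fit$converged || anyNA(cf) || any(abs(cf[!is.na(cf)]) > 1e3)) {
    log_msg("separation detected: refitting with L2 ridge (1e-4)")
    rf <- ridge_logistic(X, y, lambda = 1e-4, max_iter = 2 * max_iter, tol = tol)
    beta <- rf$coefficients
    se <- sqrt(diag(rf$vcov))
    fitted <- rf$fitted
    separated <- TRUE
  } else {
    beta <- setNames(coef(fit), c("(Intercept)", feats))
    se <- sqrt(diag(vcov(fit)))
    fitted <- fit$fitted.values
  }
  zval <- beta / se
  structure(list(coefficients = beta, se = setNames(se, names(beta)),
                 p_value = setNames(2 * pnorm(-abs(zval)), names(beta)),
                 odds_ratio = exp(beta), fitted = fitted,
                 separation = separated, features = feats),
            class = "gene_logit")
}

#' Rank genes by the fitted model
#'
#' Genes are ordered by fitted log-odds of category membership (descending;
#' ties broken by gene ID).  The `by` argument controls what is reported
#' alongside: `"score"` (log-odds, default), `"odds"` (its exponential) or
#' `"pvalue"` (one minus the fitted probability); all three are monotone
#' transforms of the linear score, so the gene ordering is identical.
#'
#' @param model A [fit_logistic()] model.
#' @param features The [build_features()] table the model was fit on.
#' @param by `"score"`, `"odds"` or `"pvalue"`.
#' @param catalog Optional [gene_catalog()] to annotate radiation status.
#' @param top Optionally truncate the report to the top `top` genes.
#' @return Data frame with `gene`, `linear_score`, `probability`, `rank`,
#'   the `by` column, `label`, and `radiation` when a catalog is given.
#' @export
rank_genes <- function(model, features, by = c("score", "odds", "pvalue"),
                       catalog = NULL, top = NULL) {
  by <- match.arg(by)
  stopifnot(inherits(model, "gene_logit"))
  X <- as.matrix(features[, model$features, drop = FALSE])
  score <- as.numeric(model$coefficients[1L] + X %*% model$coefficients[-1L])
  prob <- 1 / (1 + exp(-score))
  out <- data.frame(gene = features$gene, linear_score = score,
                    probability = prob, label = features$label,
                    stringsAsFactors = FALSE)
  out[[by]] <- switch(by, score = score, odds = exp(score), pvalue = 1 - prob)
  if (!is.null(catalog)) out$radiation <- out$gene %in% catalog$radiation_induced
  out <- out[order(-out$linear_score, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top)) out <- head(out, top)
  out
}
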