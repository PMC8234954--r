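# Partial correlation of x and y given Z from a covariance matrix, by
# inversion of the relevant submatrix (precision-matrix route).
pcor_from_cov <- function(S, x, y, Z = character()) {
  if (x == y) return(1)
  vars <- c(x, y, Z)
  P <- tryCatch(solve(S[vars, vars, drop = FALSE]),
                error = function(e) NULL)
  if (is.null(P)) stop("singular conditioning set: {", paste(Z, collapse = ", "), "}")
  r <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  max(-1, min(1, r))
}

#' Partial correlation
#'
#' Correlation of two variables after removing the linear effect of a
#' conditioning set, either by residualizing both variables on `Z`
#' (`method = "residual"`) or through the precision matrix of the covariance
#' submatrix (`method = "recursive"`).  The two routes agree to numerical
#' precision and reduce to the plain Pearson correlation for empty `Z`.
#'
#' @param x,y Variable names (columns of `data`).
#' @param Z Character vector of conditioning variable names (default empty).
#' @param data Numeric matrix, observations in rows, named columns.
#' @param method `"residual"` (default) or `"recursive"`.
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_correlation <- function(x, y, Z = character(), data,
                                method = c("residual", "recursive")) {
  method <- match.arg(method)
  if (x == y) return(1)
  if (nrow(data) <= length(Z) + 3L)
    stop("need n_obs > |Z| + 3 for a valid conditional test")
  if (method == "recursive" || length(Z) == 0L)
    return(pcor_from_cov(stats::cov(data[, c(x, y, Z), drop = FALSE]), x, y, Z))
  Zm <- cbind(1, data[, Z, drop = FALSE])
  rx <- lm.fit(Zm, data[, x])$residuals
  ry <- lm.fit(Zm, data[, y])$residuals
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("singular conditioning set: {", paste(Z, collapse = ", "), "}")
  max(-1, min(1, cor(rx, ry)))
}

#' Fisher-z conditional independence test
#'
#' Transforms a (partial) correlation with `z = atanh(rho)` and refers
#' `sqrt(n - |Z| - 3) * z` to the standard normal, two-sided.
#'
#' @param partial_corr Partial correlation (|rho| < 1; |rho| = 1 returns
#'   p = 0).
#' @param n_obs Number of observations.
#' @param z_size Size of the conditioning set.
#' @return List with `z` (the transform), `statistic` and `p_value`.
#' @export
fisher_z_test <- function(partial_corr, n_obs, z_size = 0L) {
  df <- n_obs - z_size - 3
  if (df <= 0) stop("n_obs - |Z| - 3 must be positive")
  if (abs(partial_corr) >= 1)
    return(list(z = sign(partial_corr) * Inf, statistic = sign(partial_corr) * Inf,
                p_value = 0))
  z <- atanh(partial_corr)
  stat <- sqrt(df) * z
  list(z = z, statistic = stat, p_value = 2 * pnorm(-abs(stat)))
}

# Fisher-z p-value for target/candidate given Z, from a precomputed covariance.
ci_p_value <- function(S, n_obs, x, y, Z) {
  r <- tryCatch(pcor_from_cov(S, x, y, Z), error = function(e) NA_real_)
  if (is.na(r)) return(list(r = NA_real_, p = NA_real_))
  list(r = r, p = fisher_z_test(r, n_obs, length(Z))$p_value)
}

#' Incremental association Markov blanket (IAMB)
#'
#' Forward growing phase: repeatedly admit the variable with the largest
#' absolute partial correlation with the target given the current blanket,
#' provided its Fisher-z test rejects independence at `alpha`.  Backward
#' shrinking phase: remove any member that is conditionally independent of
#' the target given the remaining blanket.  Ties in the growing phase are
#' broken lexicographically by variable name, making the output order-stable.
#'
#' @param target Target variable name.
#' @param data Numeric matrix, observations in rows, named columns (>= 2
#'   variables, >= 8 observations).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return Object of class `"markov_blanket"`: list with `target`, `blanket`
#'   (sorted character vector), `alpha`, `n_obs`.
#' @export
iamb <- function(target, data, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (ncol(data) < 2L) stop("data must contain at least 2 variables")
  if (nrow(data) < 8L) stop("need at least 8 observations")
  if (!target %in% colnames(data)) stop("target not in data: ", target)
  vars <- sort(setdiff(colnames(data), target))
  S <- stats::cov(data)
  n <- nrow(data)
  mb <- character()

  repeat {  # growing
    cands <- setdiff(vars, mb)
    if (length(cands) == 0L || n - length(mb) - 3 <= 0) break
    assoc <- vapply(cands, function(v) {
      res <- ci_p_value(S, n, target, v, mb)
      if (is.na(res$r)) -Inf else abs(res$r)
    }, numeric(1))
    best <- cands[which.max(assoc)]  # cands sorted: lexicographic tie-break
    if (!is.finite(assoc[best])) break
    p <- ci_p_value(S, n, target, best, mb)$p
    if (is.na(p) || p > alpha) break
    mb <- c(mb, best)
  }

  repeat {  # shrinking
    removed <- FALSE
    for (b in sort(mb)) {
      p <- ci_p_value(S, n, target, b, setdiff(mb, b))$p
      if (!is.na(p) && p > alpha) {
        mb <- setdiff(mb, b)
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  structure(list(target = target, blanket = sort(mb), alpha = alpha, n_obs = n),
            class = "markov_blanket")
}

# All subsets of v with size <= max_size, smallest first.
subsets_upto <- function(v, max_size) {
  out <- list(character())
  for (k in seq_len(min(length(v), max_size)))
    out <- c(out, utils::combn(v, k, simplify = FALSE))
  out
}

#' Tag blanket members as parent/child neighbors or spouses
#'
#' A member `b` of MB(X) is a spouse if some subset of `MB(X) \ {b}`
#' d-separates it from X (its influence flows only through a common child);
#' members with no separating subset are direct neighbors (parents or
#' children).  Where a spouse's separating set can be broken by adding a
#' single neighbor `c` (a collider check), `c` is oriented as a child of X.
#' Neighbors that no collider orients are reported honestly as
#' `"undetermined"` -- a Markov blanket alone cannot orient a chain.
#'
#' @param mb A `"markov_blanket"` result from [iamb()].
#' @param data The data matrix used to compute `mb`.
#' @param alpha Significance level (defaults to the blanket's).
#' @param max_sepset Largest separating-subset size searched (default 3).
#' @return The blanket with a `roles` element (named character:
#'   `"spouse"`, `"child"`, `"parent"` or `"undetermined"`).
#' @export
tag_roles <- function(mb, data, alpha = mb$alpha, max_sepset = 3L) {
  stopifnot(inherits(mb, "markov_blanket"))
  S <- stats::cov(data)
  n <- nrow(data)
  roles <- setNames(rep("undetermined", length(mb$blanket)), mb$blanket)
  sepsets <- list()
  for (b in mb$blanket) {
    rest <- setdiff(mb$blanket, b)
    rest <- rest[seq_len(min(length(rest), n - 4L))]
    for (Sset in subsets_upto(rest, max_sepset)) {
      if (n - length(Sset) - 3 <= 0) next
      p <- ci_p_value(S, n, mb$target, b, Sset)$p
      if (!is.na(p) && p > alpha) {
        roles[b] <- "spouse"
        sepsets[[b]] <- Sset
        break
      }
    }
  }
  # collider orientation: a spouse b separated by S becomes dependent again
  # given S + {c} exactly when c is a common child of X and b
  for (b in names(sepsets)) {
    for (cc in setdiff(mb$blanket, c(b, sepsets[[b]]))) {
      Sc <- c(sepsets[[b]], cc)
      if (nrow(data) - length(Sc) - 3 <= 0) next
      p <- ci_p_value(S, n, mb$target, b, Sc)$p
      if (!is.na(p) && p <= alpha && roles[cc] != "spouse") roles[cc] <- "child"
    }
  }
  mb$roles <- roles
  mb$sepsets <- sepsets
  mb
}

#' Multi-target causal network from Markov blankets
#'
#' Runs [iamb()] (and role tagging) for every target, applies the AND-rule
#' symmetry correction between targets (if X sits in MB(Y) but Y is missing
#' from MB(X), the asymmetric pair is dropped with a log entry), and
#' assembles a partially-directed graph: parents point at the target,
#' children are pointed at, spouses and undetermined members are connected by
#' role-tagged edges oriented member-to-target by convention.
#'
#' @param data Numeric matrix, observations in rows, named columns.
#' @param targets Character vector of target variables.
#' @param alpha Significance level, default 0.05.
#' @param bonferroni Divide `alpha` by the number of targets.
#' @param catalog Optional [gene_catalog()]; when given, one-to-one causal
#'   relations between radiation-induced targets and non-radiation-induced
#'   blanket members are counted.
#' @return List with `graph` (directed `igraph`, edge attribute `role`),
#'   `blankets` (named list of tagged blankets) and `one_to_one` (count or
#'   `NA` without a catalog).
#' @export
causal_network <- function(data, targets, alpha = 0.05, bonferroni = FALSE,
                           catalog = NULL) {
  if (!all(targets %in% colnames(data))) stop("all targets must be data variables")
  a <- if (bonferroni) alpha / length(targets) else alpha
  blankets <- lapply(targets, function(t) tag_roles(iamb(t, data, alpha = a), data))
  names(blankets) <- targets

  # AND-rule between targets
  for (t in targets) for (b in intersect(blankets[[t]]$blanket, targets)) {
    if (!t %in% blankets[[b]]$blanket) {
      log_msg("AND-rule: dropping asymmetric pair %s ~ %s", t, b)
      keep <- setdiff(blankets[[t]]$blanket, b)
      blankets[[t]]$blanket <- keep
      blankets[[t]]$roles <- blankets[[t]]$roles[keep]
    }
  }

  ef <- character(); et <- character(); er <- character()
  for (t in targets) {
    roles <- blankets[[t]]$roles
    for (b in blankets[[t]]$blanket) {
      if (identical(roles[[b]], "child")) { ef <- c(ef, t); et <- c(et, b) }
      else { ef <- c(ef, b); et <- c(et, t) }
      er <- c(er, roles[[b]])
    }
  }
  edges <- unique(data.frame(from = ef, to = et, role = er, stringsAsFactors = FALSE))
  nodes <- unique(c(targets, edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))

  one_to_one <- NA_integer_
  if (!is.null(catalog)) {
    rad <- catalog$radiation_induced
    one_to_one <- sum(vapply(targets, function(t) {
      if (t %in% rad) sum(!blankets[[t]]$blanket %in% rad) else 0L
    }, integer(1)))
  }
  list(graph = g, blankets = blankets, one_to_one = one_to_one)
}
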