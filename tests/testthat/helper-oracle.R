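# Independent brute-force oracles. These deliberately share no code with
# the package internals: subsets are materialized and impurities computed
# by direct arithmetic.

oracle_gini <- function(pos, neg) {
  p <- pos / (pos + neg)
  1 - p^2 - (1 - p)^2
}

# exhaustive enumeration of every (column, cutpoint) split; same tie
# discipline as the package contract: an improvement must beat the
# incumbent by > tol, columns scanned in order, cutpoints ascending.
oracle_best_split <- function(X, y, class_weight = 5, min_leaf = 1L,
                              tol = 1e-10) {
  w <- ifelse(y == 1, class_weight, 1)
  W <- sum(w); WP <- sum(w * y)
  g_parent <- oracle_gini(WP, W - WP)
  best <- NULL
  for (j in seq_along(X)) {
    vals <- sort(unique(X[[j]]))
    for (v in vals[-1]) { # left branch: x < v
      left <- X[[j]] < v
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      wl <- sum(w[left]); wpl <- sum((w * y)[left])
      wr <- sum(w[!left]); wpr <- sum((w * y)[!left])
      dec <- g_parent - (wl * oracle_gini(wpl, wl - wpl) +
                           wr * oracle_gini(wpr, wr - wpr)) / W
      if (is.null(best) || dec > best$decrease + tol)
        best <- list(col = names(X)[j], cut = v, decrease = dec,
                     risk_left = wpl / wl, risk_right = wpr / wr)
    }
  }
  best
}

# recursive greedy tree matching the fitting contract, built on the
# enumeration oracle
oracle_tree <- function(X, y, max_depth, min_leaf, class_weight) {
  w <- ifelse(y == 1, class_weight, 1)
  risk <- sum(w * y) / sum(w)
  if (max_depth == 0 || length(unique(y)) < 2)
    return(list(leaf = TRUE, risk = risk))
  s <- oracle_best_split(X, y, class_weight, min_leaf)
  if (is.null(s) || s$decrease <= 1e-12) return(list(leaf = TRUE, risk = risk))
  left <- X[[s$col]] < s$cut
  list(leaf = FALSE, col = s$col, cut = s$cut,
       left = oracle_tree(X[left, , drop = FALSE], y[left],
                          max_depth - 1, min_leaf, class_weight),
       right = oracle_tree(X[!left, , drop = FALSE], y[!left],
                           max_depth - 1, min_leaf, class_weight))
}

# canonical string of a fitted cart_tree node ('yes' = condition true)
canon_pkg_tree <- function(node) {
  if (node$leaf) return(sprintf("L[%.10f]", node$risk))
  cc <- node$condition
  # orient to (x < cut) left / (x >= cut) right regardless of condition form
  if (cc$op == "==" && cc$threshold == 1) {
    sprintf("S[%s<1](%s)(%s)", cc$predictor, canon_pkg_tree(node$no),
            canon_pkg_tree(node$yes))
  } else if (cc$op == "<") {
    sprintf("S[%s<%s](%s)(%s)", cc$predictor, cc$threshold,
            canon_pkg_tree(node$yes), canon_pkg_tree(node$no))
  } else {
    stop("unexpected condition form in canon_pkg_tree")
  }
}

canon_oracle_tree <- function(node) {
  if (node$leaf) return(sprintf("L[%.10f]", node$risk))
  sprintf("S[%s<%s](%s)(%s)", node$col, node$cut,
          canon_oracle_tree(node$left), canon_oracle_tree(node$right))
}

# direct arithmetic Cohen's kappa with the Fleiss-Cohen-Everitt SE from
# the four cell counts of the 2x2 agreement table
oracle_kappa <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p11 <- n11 / n; p10 <- n10 / n; p01 <- n01 / n; p00 <- n00 / n
  pa1 <- p11 + p10; pb1 <- p11 + p01 # marginal "yes" rates
  po <- p11 + p00
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  k <- (po - pe) / (1 - pe)
  A <- p11 * (1 - (pa1 + pb1) * (1 - k))^2 +
    p00 * (1 - ((1 - pa1) + (1 - pb1)) * (1 - k))^2
  B <- (1 - k)^2 * (p10 * (pb1 + (1 - pa1))^2 + p01 * ((1 - pb1) + pa1)^2)
  C <- (k - pe * (1 - k))^2
  se <- sqrt((A + B - C) / (n * (1 - pe)^2))
  list(kappa = k, se = se, ci_low = k - 1.96 * se, ci_high = k + 1.96 * se)
}

# phi from the 2x2 table by direct arithmetic
oracle_phi <- function(n11, n10, n01, n00) {
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

# vectors -> agreement cells
agreement_cells <- function(a, b) {
  c(n11 = sum(a == 1 & b == 1), n10 = sum(a == 1 & b == 0),
    n01 = sum(a == 0 & b == 1), n00 = sum(a == 0 & b == 0))
}
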