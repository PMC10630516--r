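#' Shared-allele distance between individuals
#'
#' `D(i, j) = 1 - mean over comparable loci of (shared alleles / 2)`, where
#' the shared-allele count at a locus is the multiset intersection size of
#' the two diploid calls (0, 1 or 2) and a locus is comparable when both
#' individuals are genotyped there. `D(i, i) = 0`. A pair with no
#' comparable locus gets an `NA` cell (tree construction then refuses).
#'
#' @param g A genotype table with at least two individuals.
#' @return Symmetric numeric matrix with individual dimnames.
#' @export
individual_distances <- function(g) {
  g <- as_genotypes(g)
  inds <- gt_individuals(g)
  if (length(inds) < 2) {
    stop("at least two individuals are required", call. = FALSE)
  }
  loci <- gt_loci(g)
  tab <- tibble::as_tibble(g)
  a1 <- matrix(NA_integer_, length(inds), length(loci),
    dimnames = list(inds, loci)
  )
  a2 <- a1
  a1[cbind(tab$individual, tab$locus)] <- tab$allele_1
  a2[cbind(tab$individual, tab$locus)] <- tab$allele_2

  n <- length(inds)
  d <- matrix(0, n, n, dimnames = list(inds, inds))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(a1[i, ]) & !is.na(a1[j, ])
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      shared <- shared_allele_count(a1[i, ok], a2[i, ok], a1[j, ok], a2[j, ok])
      d[i, j] <- d[j, i] <- 1 - mean(shared / 2)
    }
  }
  d
}

# multiset intersection size (0, 1 or 2) of two diploid calls per locus:
# count per distinct allele the minimum multiplicity in the two calls
shared_allele_count <- function(x1, x2, y1, y2) {
  out <- integer(length(x1))
  for (k in seq_along(x1)) {
    a <- c(x1[k], x2[k])
    b <- c(y1[k], y2[k])
    s <- 0L
    for (al in unique(a)) {
      s <- s + min(sum(a == al), sum(b == al))
    }
    out[k] <- s
  }
  out
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with cluster sizes as weights; node heights
#' are half the joining distance, so the tree is ultrametric. Ties are broken
#' by the smallest pair of label indices, making the output deterministic.
#'
#' @param d Symmetric distance matrix with dimnames (or a `dist`).
#' @return An [ape::phylo] rooted ultrametric tree; serialize with
#'   [ape::write.tree()].
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (anyNA(d[upper.tri(d)])) {
    stop("distance matrix has NA cells; UPGMA needs a complete matrix",
      call. = FALSE
    )
  }
  if (max(abs(d - t(d))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }

  labels <- rownames(d)
  n <- nrow(d)
  # active clusters: newick fragment, height, size, smallest member index
  newick <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  min_leaf <- seq_len(n)
  active <- seq_len(n)
  dm <- d

  while (length(active) > 1) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]
        j <- active[jj]
        if (is.null(best) || dm[i, j] < best$d - 1e-15) {
          best <- list(i = i, j = j, d = dm[i, j])
        }
      }
    }
    i <- best$i
    j <- best$j
    h <- best$d / 2
    new_id <- length(newick) + 1L
    # child containing the smallest original leaf prints first
    if (min_leaf[j] < min_leaf[i]) {
      tmp <- i
      i <- j
      j <- tmp
    }
    newick[new_id] <- sprintf(
      "(%s:%.10g,%s:%.10g)",
      newick[i], h - height[i], newick[j], h - height[j]
    )
    height[new_id] <- h
    size[new_id] <- size[i] + size[j]
    min_leaf[new_id] <- min(min_leaf[i], min_leaf[j])
    # size-weighted average linkage (UPGMA)
    others <- setdiff(active, c(i, j))
    dm <- rbind(cbind(dm, 0), 0)
    for (k in others) {
      dm[new_id, k] <- dm[k, new_id] <-
        (size[i] * dm[i, k] + size[j] * dm[j, k]) / (size[i] + size[j])
    }
    active <- c(others, new_id)
  }
  ape::read.tree(text = paste0(newick[active], ";"))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and keeps the axes with
#' positive eigenvalues; coordinates are eigenvectors scaled by the square
#' root of their eigenvalue, and each axis's variance share is its
#' eigenvalue over the sum of positive eigenvalues (negative eigenvalues
#' are dropped from the denominator and counted in `n_negative_eig`). The
#' sign of each axis is fixed so its first nonzero loading is positive.
#'
#' @param d Symmetric distance matrix with dimnames (or a `dist`).
#' @return An object of class `ssr_pcoa` with elements `points` (tibble:
#'   `individual`, `Axis1`, ...), `eig` (positive eigenvalues),
#'   `var_pct` (percent variance per axis) and `n_negative_eig`.
#' @export
pcoa <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (anyNA(d)) stop("distance matrix has NA cells", call. = FALSE)
  n <- nrow(d)
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("i", seq_len(n))
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-9 & e$values > 1e-12)
  n_neg <- sum(e$values < -1e-9 * max(abs(e$values)))
  if (length(pos) == 0) {
    return(structure(
      list(
        points = tibble::tibble(individual = labs), eig = numeric(0),
        var_pct = numeric(0), n_negative_eig = n_neg
      ),
      class = "ssr_pcoa"
    ))
  }
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  for (k in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, k]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], k] < 0) coords[, k] <- -coords[, k]
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  if (n_neg > 0) {
    message(n_neg, " negative eigenvalue(s) dropped from the variance ",
      "denominator"
    )
  }
  structure(
    list(
      points = dplyr::bind_cols(
        tibble::tibble(individual = labs), tibble::as_tibble(coords)
      ),
      eig = e$values[pos],
      var_pct = 100 * e$values[pos] / sum(e$values[pos]),
      n_negative_eig = n_neg
    ),
    class = "ssr_pcoa"
  )
}

#' @export
print.ssr_pcoa <- function(x, ...) {
  cat(sprintf(
    "<ssr_pcoa> %d points, %d axes; axis 1-2 variance: %s%%\n",
    nrow(x$points), length(x$eig),
    paste(sprintf("%.2f", utils::head(x$var_pct, 2)), collapse = " / ")
  ))
  invisible(x)
}

#' @method tidy ssr_pcoa
#' @export
tidy.ssr_pcoa <- function(x, ...) x$points

#' @method glance ssr_pcoa
#' @export
glance.ssr_pcoa <- function(x, ...) {
  tibble::tibble(
    n_axes = length(x$eig),
    axis1_pct = if (length(x$var_pct) >= 1) x$var_pct[1] else NA_real_,
    axis2_pct = if (length(x$var_pct) >= 2) x$var_pct[2] else NA_real_,
    n_negative_eig = x$n_negative_eig
  )
}

#' @method autoplot ssr_pcoa
#' @export
autoplot.ssr_pcoa <- function(object, colour_by = NULL, ...) {
  d <- object$points
  mapping <- ggplot2::aes(.data$Axis1, .data$Axis2)
  if (!is.null(colour_by)) {
    d$group <- colour_by[d$individual]
    mapping <- ggplot2::aes(.data$Axis1, .data$Axis2, colour = .data$group)
  }
  p <- ggplot2::ggplot(d, mapping) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.2f%%)", object$var_pct[1]),
      y = sprintf("Axis 2 (%.2f%%)", object$var_pct[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  p
}

#' Evanno delta-K from STRUCTURE run likelihoods
#'
#' Post-processes a table of STRUCTURE replicate log-likelihoods LnP(D) into
#' the Evanno statistics: per K the mean and sample standard deviation of
#' L(K) over runs, the first difference `L'(K) = L(K) - L(K-1)`, the
#' absolute second difference `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `deltaK = |L''(K)| / sd(L(K))`, defined for interior K only. `best_K`
#' maximizes deltaK.
#'
#' @param runs Tibble with columns `K`, `run`, `lnPD` (see
#'   [read_structure_runs()]); K must cover at least three consecutive
#'   values with at least two runs each.
#' @return An object of class `deltak`: a tibble with columns `K`,
#'   `n_runs`, `mean_lnPD`, `sd_lnPD`, `lprime`, `lsecond`, `delta_K`, with
#'   attribute `best_K`.
#' @export
evanno_deltak <- function(runs) {
  stopifnot(all(c("K", "run", "lnPD") %in% names(runs)))
  smry <- runs |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_lnPD = mean(.data$lnPD),
      sd_lnPD = stats::sd(.data$lnPD),
      .by = "K"
    ) |>
    dplyr::arrange(.data$K)
  ks <- smry$K
  if (length(ks) < 3 || any(diff(ks) != 1)) {
    stop("delta-K needs at least three consecutive K values", call. = FALSE)
  }
  if (any(smry$n_runs < 2)) {
    stop("delta-K needs at least two runs per K (sd is undefined otherwise)",
      call. = FALSE
    )
  }
  m <- smry$mean_lnPD
  lprime <- c(NA, diff(m))
  lsecond <- abs(c(NA, diff(lprime)[-1], NA)) # |L'(K+1) - L'(K)| interior
  zero_sd <- smry$sd_lnPD == 0
  if (any(zero_sd & !is.na(lsecond))) {
    warning("sd of L(K) is zero at K = ",
      paste(smry$K[zero_sd], collapse = ","), "; delta-K undefined there"
    )
  }
  delta <- ifelse(smry$sd_lnPD > 0, lsecond / smry$sd_lnPD, NA_real_)
  out <- dplyr::mutate(smry,
    lprime = lprime, lsecond = lsecond, delta_K = delta
  )
  best <- if (all(is.na(delta))) NA_integer_ else ks[which.max(delta)]
  structure(out,
    class = c("deltak", class(out)),
    best_K = best
  )
}

#' @method tidy deltak
#' @export
tidy.deltak <- function(x, ...) {
  tibble::as_tibble(unclass(x)[
    c("K", "n_runs", "mean_lnPD", "sd_lnPD", "lprime", "lsecond", "delta_K")
  ])
}

#' @method glance deltak
#' @export
glance.deltak <- function(x, ...) {
  tibble::tibble(
    best_K = attr(x, "best_K"),
    max_delta_K = suppressWarnings(max(x$delta_K, na.rm = TRUE))
  )
}

#' @method autoplot deltak
#' @export
autoplot.deltak <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d[!is.na(d$delta_K), ],
    ggplot2::aes(.data$K, .data$delta_K)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "K", y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}
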