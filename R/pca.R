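#' Principal component analysis with direct oblimin rotation
#'
#' Eigendecomposes the correlation matrix of the supplied measures, retains
#' the leading `n_components` components, and applies a direct oblimin
#' (gamma = 0, i.e. quartimin) oblique rotation to the loading matrix using
#' the gradient-projection algorithm, with Kaiser row normalization by
#' default. Oblique rotation leaves each measure's communality unchanged, so
#' uniqueness is reported as 1 - communality from the unrotated solution.
#'
#' Component signs are indeterminate; each column is flipped so its dominant
#' loadings are positive. Columns are ordered by explained variance of the
#' unrotated components.
#'
#' @param data A data frame of measures (rows = participants).
#' @param measures Character vector of measure columns (default: all).
#' @param n_components Number of components to retain (default 3).
#' @param kaiser Apply Kaiser normalization before rotation (default TRUE).
#' @param gamma Oblimin family parameter (0 = direct oblimin / quartimin).
#' @param max_iter,tol Gradient-projection iteration controls.
#' @return A `pca_oblimin` object: `pattern` (measures x components pattern
#'   loadings), `uniqueness` (named vector in `[0, 1]`), `phi` (component
#'   correlations), `eigenvalues`, `n`, `converged`. `tidy()` returns the
#'   loadings in long form.
#' @export
pca_oblimin <- function(data, measures = NULL, n_components = 3,
                        kaiser = TRUE, gamma = 0,
                        max_iter = 1000, tol = 1e-6) {
  data <- as_tibble(data)
  measures <- measures %||% names(data)
  if (length(measures) < 3) abort("need at least 3 measures")
  x <- as.matrix(data[measures])
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) <= ncol(x)) abort("need more rows than measures")
  if (any(apply(x, 2, sd) == 0)) abort("constant measure: correlation undefined")

  r <- cor(x)
  eig <- eigen(r, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    abort("correlation matrix is not positive semi-definite")
  }
  if (n_components > sum(eig$values > 1e-10)) {
    abort("more components requested than positive eigenvalues")
  }
  a <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(n_components)]), n_components)
  rownames(a) <- measures

  h2 <- rowSums(a^2)
  w <- if (kaiser) sqrt(h2) else rep(1, length(h2))
  rot <- oblimin_rotate(a / w, gamma = gamma, max_iter = max_iter, tol = tol)
  pattern <- rot$loadings * w
  phi <- rot$phi

  # resolve sign indeterminacy: dominant direction of each column positive
  flip <- sign(colSums(pattern^3))
  flip[flip == 0] <- 1
  pattern <- sweep(pattern, 2, flip, `*`)
  phi <- diag(flip) %*% phi %*% diag(flip)
  colnames(pattern) <- paste0("RC", seq_len(n_components))
  dimnames(phi) <- list(colnames(pattern), colnames(pattern))

  structure(
    list(
      pattern = pattern,
      uniqueness = setNames(pmin(pmax(1 - h2, 0), 1), measures),
      phi = phi,
      eigenvalues = eig$values,
      n = nrow(x),
      converged = rot$converged
    ),
    class = "pca_oblimin"
  )
}

# Gradient-projection oblique rotation (Jennrich 2002 family) minimizing the
# oblimin criterion f(L) = sum_i sum_{j != k} w_ij L2_ij L2_ik / 4 over
# oblique rotations T with unit-length columns, where L = A t(solve(T)).
oblimin_rotate <- function(a, gamma = 0, max_iter = 1000, tol = 1e-6) {
  k <- ncol(a)
  if (k == 1) {
    return(list(loadings = a, tmat = diag(1), phi = diag(1), converged = TRUE))
  }
  vg <- function(l) {
    n_off <- matrix(1, k, k) - diag(k)
    x <- l^2 %*% n_off
    if (gamma != 0) {
      p <- nrow(l)
      x <- (diag(p) - matrix(gamma / p, p, p)) %*% x
    }
    list(f = sum(l^2 * x) / 4, gq = l * x)
  }
  tmat <- diag(k)
  al <- 1
  l <- a %*% t(solve(tmat))
  v <- vg(l)
  f <- v$f
  g <- -t(t(l) %*% v$gq %*% solve(tmat))
  s <- Inf
  for (iter in seq_len(max_iter)) {
    gp <- g - tmat %*% diag(colSums(tmat * g), k)
    s <- sqrt(sum(gp^2))
    if (s < tol) break
    al <- 2 * al
    for (i in 0:20) {
      x <- tmat - al * gp
      tt <- x %*% diag(1 / sqrt(colSums(x^2)), k)
      l <- a %*% t(solve(tt))
      vt <- vg(l)
      if (vt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    tmat <- tt
    f <- vt$f
    g <- -t(t(l) %*% vt$gq %*% solve(tt))
  }
  list(
    loadings = a %*% t(solve(tmat)), tmat = tmat,
    phi = t(tmat) %*% tmat, converged = s < tol
  )
}

#' @export
print.pca_oblimin <- function(x, ..., cutoff = 0.3) {
  cat(sprintf(
    "<pca_oblimin> %d measures, %d components, n = %d\n",
    nrow(x$pattern), ncol(x$pattern), x$n
  ))
  pat <- formatC(x$pattern, format = "f", digits = 3)
  pat[abs(x$pattern) < cutoff] <- ""
  print(cbind(as.data.frame(pat), uniqueness = round(x$uniqueness, 3)))
  invisible(x)
}

#' @export
tidy.pca_oblimin <- function(x, ...) {
  as_tibble(x$pattern, rownames = "measure") %>%
    pivot_longer(-"measure", names_to = "component", values_to = "loading") %>%
    left_join(
      tibble(measure = names(x$uniqueness), uniqueness = unname(x$uniqueness)),
      by = "measure"
    )
}

#' Select one measure per task from an oblimin-rotated PCA
#'
#' Attributes each rotated component to the task holding the majority of its
#' absolute pattern-loading mass, then, for every task, selects the measure
#' with the largest absolute loading on that task's component. Used to pick
#' one discriminating metric per task for the combined regression model.
#'
#' @param pca A `pca_oblimin` object whose measures span all tasks.
#' @param task_of_measure Named character vector mapping measure name to
#'   task id.
#' @return A tibble with one row per task: `task`, `component`, `measure`,
#'   `loading`.
#' @export
select_combined_metrics <- function(pca, task_of_measure) {
  stopifnot(inherits(pca, "pca_oblimin"))
  pat <- pca$pattern
  missing <- setdiff(rownames(pat), names(task_of_measure))
  if (length(missing)) {
    abort(paste0("no task mapping for measure(s): ", paste(missing, collapse = ", ")))
  }
  tasks <- task_of_measure[rownames(pat)]
  # component -> task by |loading| mass
  mass <- rowsum(abs(pat), group = tasks)
  comp_task <- rownames(mass)[apply(mass, 2, which.max)]
  if (anyDuplicated(comp_task) || !setequal(comp_task, unique(tasks))) {
    abort("components are not attributable to unique tasks")
  }
  out <- map(seq_len(ncol(pat)), function(j) {
    members <- which(tasks == comp_task[j])
    best <- members[which.max(abs(pat[members, j]))]
    tibble(
      task = comp_task[j], component = colnames(pat)[j],
      measure = rownames(pat)[best], loading = pat[best, j]
    )
  })
  bind_rows(out) %>% arrange(.data$task)
}
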