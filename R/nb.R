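# Naive Bayes on term counts, mirroring the kernel / no-kernel
# distribution-type dichotomy: "no kernel" fits a Gaussian per term and
# class, "kernel" a per-term kernel density estimate. The Laplace
# correction floors per-term likelihoods at `laplace * 1e-3` so rare or
# unseen feature values never zero out the multiplicative posterior.

NB_SD_FLOOR <- 1e-3
NB_LAPLACE_UNIT <- 1e-3

nb_fit <- function(x, y, kernel = FALSE, laplace = 0) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("include", "exclude"))
  if (any(table(y) == 0)) fail("naive Bayes requires both classes in training data")
  classes <- levels(y)
  prior <- as.numeric(table(y)[classes]) / length(y)
  stats <- lapply(classes, function(cls) {
    xc <- x[y == cls, , drop = FALSE]
    mu <- colMeans(xc)
    sdev <- apply(xc, 2, stats::sd)
    sdev[is.na(sdev)] <- 0
    dens <- NULL
    if (kernel) {
      dens <- lapply(seq_len(ncol(xc)), function(j) {
        v <- xc[, j]
        if (stats::sd(v) == 0) return(NULL)  # degenerate: fall back to a narrow Gaussian spike
        d <- stats::density(v, n = 256)
        list(x = d$x, y = d$y)
      })
    }
    list(mu = mu, sd = sdev, dens = dens)
  })
  names(stats) <- classes
  structure(list(classes = classes, prior = prior, stats = stats,
                 kernel = kernel, laplace = laplace,
                 vocabulary = colnames(x)), class = "picoscreen_nb")
}

# Per-class log-likelihood matrix (rows = observations).
nb_class_loglik <- function(fit, x, cls) {
  st <- fit$stats[[cls]]
  p <- ncol(x)
  n <- nrow(x)
  ll <- matrix(0, n, p)
  if (!fit$kernel) {
    sd_adj <- pmax(st$sd, NB_SD_FLOOR)
    for (j in seq_len(p)) {
      ll[, j] <- stats::dnorm(x[, j], st$mu[j], sd_adj[j], log = TRUE)
    }
  } else {
    for (j in seq_len(p)) {
      d <- st$dens[[j]]
      if (is.null(d)) {
        ll[, j] <- stats::dnorm(x[, j], st$mu[j], NB_SD_FLOOR, log = TRUE)
      } else {
        f <- stats::approx(d$x, d$y, xout = x[, j], yleft = 0, yright = 0)$y
        ll[, j] <- log(f)
      }
    }
  }
  floor_ll <- if (fit$laplace > 0) log(fit$laplace * NB_LAPLACE_UNIT) else log(.Machine$double.xmin)
  pmax(ll, floor_ll)
}

# Posterior probability of the "exclude" class.
nb_predict <- function(fit, x) {
  x <- as.matrix(x)
  scores <- vapply(seq_along(fit$classes), function(k) {
    log(fit$prior[k]) + rowSums(nb_class_loglik(fit, x, fit$classes[k]))
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  m <- apply(scores, 1, max)
  w <- exp(scores - m)
  post <- w / rowSums(w)
  post[, match("exclude", fit$classes)]
}
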