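#' Width population
#'
#' A collection of per-cell widths with the image each cell came from, the
#' unit on which population statistics (expansion ratio, classification)
#' operate. Replicate images are the clustering unit for bootstrap errors.
#'
#' @param widths_um Positive cell widths in um.
#' @param image_ids Per-width image identifier (recycled if scalar).
#' @return Object of class `width_population`.
#' @export
width_population <- function(widths_um, image_ids = 1L) {
  widths_um <- as.numeric(widths_um)
  if (length(widths_um) && any(!is.finite(widths_um) | widths_um <= 0))
    stop("widths must be positive and finite", call. = FALSE)
  if (length(image_ids) == 1L) image_ids <- rep(image_ids, length(widths_um))
  if (length(image_ids) != length(widths_um))
    stop("image_ids must match widths_um in length", call. = FALSE)
  structure(list(widths_um = widths_um, image_ids = as.character(image_ids),
                 n_images = length(unique(image_ids))),
            class = "width_population")
}

#' Expansion ratio with cluster-bootstrap SEM
#'
#' The expansion ratio is the mean post-expansion cell width divided by the
#' mean pre-expansion cell width. Its SEM is estimated by a cluster
#' bootstrap: whole images are resampled with replacement (independently in
#' the pre and post arms) and the ratio recomputed, respecting the
#' correlation of cells within an image. When an arm has a single image the
#' bootstrap falls back to resampling cells, with a warning.
#'
#' @param pre,post [width_population()] objects.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `expansion_result`: list `ratio`, `sem`, `n_pre`,
#'   `n_post`.
#' @export
expansion_ratio <- function(pre, post, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(pre, "width_population"),
            inherits(post, "width_population"))
  if (!length(pre$widths_um) || !length(post$widths_um))
    stop("both populations must be nonempty", call. = FALSE)
  ratio <- mean(post$widths_um) / mean(pre$widths_um)
  boot_mean <- function(pop) {
    ids <- unique(pop$image_ids)
    if (length(ids) == 1L) {
      function() mean(sample(pop$widths_um, length(pop$widths_um),
                             replace = TRUE))
    } else {
      by_img <- split(pop$widths_um, pop$image_ids)
      function() {
        pick <- sample(names(by_img), length(by_img), replace = TRUE)
        mean(unlist(by_img[pick], use.names = FALSE))
      }
    }
  }
  if (pre$n_images == 1L || post$n_images == 1L)
    warning("single image in a population: SEM from resampling cells")
  set.seed(seed)
  f_pre <- boot_mean(pre)
  f_post <- boot_mean(post)
  boots <- vapply(seq_len(n_boot), function(i) f_post() / f_pre(), numeric(1))
  structure(list(ratio = ratio, sem = stats::sd(boots),
                 n_pre = length(pre$widths_um),
                 n_post = length(post$widths_um)),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf("Expansion ratio %.3f +/- %.3f (SEM; n_pre = %d, n_post = %d)\n",
              x$ratio, x$sem, x$n_pre, x$n_post))
  invisible(x)
}

#' Fit a single-species reference width model
#'
#' Mean and SD of a control population containing a single species, used as
#' the class-conditional normal for width-based classification. An SD floor
#' (default half a pixel at 0.1 um/px) guards against zero-variance
#' likelihoods from quantized measurements.
#'
#' @param widths A [width_population()] with at least 20 cells.
#' @param species Species label.
#' @param prior Prior probability (set externally; default NA, treated as
#'   equal priors by [classify_widths()]).
#' @param sd_floor_um SD floor in um (default 0.05 = half a 0.1-um pixel).
#' @return Object of class `reference_model`.
#' @export
fit_reference <- function(widths, species, prior = NA_real_,
                          sd_floor_um = 0.05) {
  stopifnot(inherits(widths, "width_population"))
  if (length(widths$widths_um) < 20L)
    stop("at least 20 widths required to fit a reference", call. = FALSE)
  s <- stats::sd(widths$widths_um)
  structure(list(species = species, mean_um = mean(widths$widths_um),
                 sd_um = max(s, sd_floor_um), prior = prior,
                 n = length(widths$widths_um)),
            class = "reference_model")
}

#' Classify cell widths against species references
#'
#' Assigns each width to the reference maximizing the normal likelihood
#' times the prior (equal priors when unset). Posterior ties break toward
#' the smaller-mean reference, deterministically.
#'
#' @param widths A [width_population()].
#' @param references List of `reference_model` objects with distinct means.
#' @return List with `assignments` (character vector of species per cell)
#'   and `composition` (class `mixture_composition`: data.frame `species`,
#'   `count`, `fraction`, plus attribute `n_total`).
#' @export
classify_widths <- function(widths, references) {
  stopifnot(inherits(widths, "width_population"))
  if (inherits(references, "reference_model")) references <- list(references)
  if (!length(references)) stop("need at least one reference", call. = FALSE)
  stopifnot(all(vapply(references, inherits, TRUE, "reference_model")))
  mu <- vapply(references, `[[`, numeric(1), "mean_um")
  if (anyDuplicated(mu)) stop("references must have distinct means", call. = FALSE)
  # order by ascending mean so which.max's first-match rule implements the
  # smaller-mean tie-break
  ord <- order(mu)
  references <- references[ord]
  mu <- mu[ord]
  sd <- vapply(references, `[[`, numeric(1), "sd_um")
  pr <- vapply(references, `[[`, numeric(1), "prior")
  if (anyNA(pr)) pr <- rep(1 / length(references), length(references))
  pr <- pr / sum(pr)
  sp <- vapply(references, `[[`, character(1), "species")
  w <- widths$widths_um
  ll <- vapply(seq_along(references), function(j)
    stats::dnorm(w, mu[j], sd[j], log = TRUE) + log(pr[j]),
    numeric(length(w)))
  ll <- matrix(ll, nrow = length(w))
  pick <- apply(ll, 1L, which.max)
  assignments <- sp[pick]
  counts <- vapply(sp, function(s) sum(assignments == s), integer(1))
  comp <- data.frame(species = sp, count = as.integer(counts),
                     fraction = if (length(w)) counts / length(w) else
                       rep(NaN, length(sp)),
                     row.names = NULL)
  attr(comp, "n_total") <- length(w)
  class(comp) <- c("mixture_composition", "data.frame")
  list(assignments = assignments, composition = comp)
}

#' Classify cell widths by a fixed threshold
#'
#' Two-population split at a fixed width cutoff, the simple alternative to
#' posterior classification when two in vivo populations are separated by a
#' clear valley (e.g. unexpanded vs ~2x-expanded cells). Widths strictly
#' below the cutoff go to the first label.
#'
#' @param widths A [width_population()].
#' @param cutoff_um Width threshold in um.
#' @param labels Two class labels, small then large (default
#'   `c("below", "above")`).
#' @return As [classify_widths()]: list with `assignments` and `composition`.
#' @export
classify_by_threshold <- function(widths, cutoff_um,
                                  labels = c("below", "above")) {
  stopifnot(inherits(widths, "width_population"), length(labels) == 2L)
  if (cutoff_um <= 0) stop("cutoff_um must be positive", call. = FALSE)
  w <- widths$widths_um
  assignments <- ifelse(w < cutoff_um, labels[1], labels[2])
  counts <- c(sum(w < cutoff_um), sum(w >= cutoff_um))
  comp <- data.frame(species = labels, count = as.integer(counts),
                     fraction = if (length(w)) counts / length(w) else
                       rep(NaN, 2L),
                     row.names = NULL)
  attr(comp, "n_total") <- length(w)
  class(comp) <- c("mixture_composition", "data.frame")
  list(assignments = assignments, composition = comp)
}

#' Fit a 1D Gaussian mixture to cell widths by EM
#'
#' For populations without single-species controls: fits a k-component
#' univariate Gaussian mixture by expectation-maximization, initialized from
#' the sample quantiles (deterministic given `seed`, which only perturbs the
#' initialization). Components are returned sorted by ascending mean as
#' `reference_model` objects with the mixing weights as priors. Components
#' whose `mean +/- 2 sd` intervals overlap are flagged `unresolved`.
#'
#' @param widths A [width_population()] with at least `10 * k` cells.
#' @param k Number of components.
#' @param seed Integer seed.
#' @param max_iter,tol EM stopping rule (default 500 iterations, 1e-8
#'   relative log-likelihood change).
#' @return List of `reference_model`s with attributes `converged`,
#'   `loglik`, `unresolved`.
#' @export
fit_mixture <- function(widths, k, seed = 1L, max_iter = 500L, tol = 1e-8) {
  stopifnot(inherits(widths, "width_population"), k >= 1L)
  x <- widths$widths_um
  n <- length(x)
  if (n < 10L * k)
    stop("need at least 10 * k widths to fit a mixture", call. = FALSE)
  if (k == 1L) {
    out <- list(fit_reference(widths, species = "component_1", prior = 1))
    attr(out, "converged") <- TRUE
    attr(out, "loglik") <- sum(stats::dnorm(x, mean(x), stats::sd(x), log = TRUE))
    attr(out, "unresolved") <- FALSE
    return(out)
  }
  set.seed(seed)
  mu <- as.numeric(stats::quantile(x, (2 * seq_len(k) - 1) / (2 * k))) +
    stats::rnorm(k, 0, stats::sd(x) * 1e-3)
  sg <- rep(stats::sd(x) / k, k)
  sg <- pmax(sg, 1e-6)
  wts <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) wts[j] * stats::dnorm(x, mu[j], sg[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk == 0] <- 1e-12
    wts <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    sg <- pmax(sg, 1e-4)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("EM did not converge within max_iter; returning best-so-far fit")
  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]; wts <- wts[ord]
  out <- lapply(seq_len(k), function(j)
    structure(list(species = paste0("component_", j), mean_um = mu[j],
                   sd_um = sg[j], prior = wts[j], n = n),
              class = "reference_model"))
  overlap <- any(mu[-k] + 2 * sg[-k] > mu[-1] - 2 * sg[-1])
  attr(out, "converged") <- converged
  attr(out, "loglik") <- ll
  attr(out, "unresolved") <- overlap
  out
}

#' Detect DNA-halo phenotypes
#'
#' For each segmented cytoplasm label, measures the cell width and the width
#' of the DNA cloud in the registered DNA channel, and calls the cell
#' "expanded" (halo phenotype, i.e. translocated chromosome) when the
#' DNA-to-cytoplasm width ratio reaches `cutoff`. The DNA cloud is found by
#' Otsu-thresholding the DNA channel inside a window (the cell bounding box
#' dilated by five cytoplasm widths), labelling the window's components and
#' keeping the one overlapping the cell the most; its width is measured with
#' the same five-station chord procedure as the cell. Cells with no DNA
#' signal overlapping them are skipped with a message.
#'
#' @param cyto_labels A `label_image` of the cytoplasm channel.
#' @param dna_image Numeric matrix, registered DNA channel.
#' @param cutoff Width-ratio cutoff, > 1 (default 2, midway between the
#'   unexpanded ratio ~1 and the full halo ~4).
#' @return data.frame: `label`, `cyto_width_um`, `dna_width_um`, `ratio`,
#'   `expanded`.
#' @export
detect_halo <- function(cyto_labels, dna_image, cutoff = 2) {
  stopifnot(inherits(cyto_labels, "label_image"))
  if (cutoff <= 1) stop("cutoff must be > 1", call. = FALSE)
  if (!all(dim(dna_image) == dim(cyto_labels$labels)))
    stop("channels are not registered (dimension mismatch)", call. = FALSE)
  px <- cyto_labels$pixel_size_um
  cells <- measure_cells(cyto_labels)
  L <- cyto_labels$labels
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    lab <- cells$label[i]
    idx <- which(L == lab)
    rr <- (idx - 1L) %% nrow(L) + 1L
    cc <- (idx - 1L) %/% nrow(L) + 1L
    wpx <- cells$width_um[i] / px
    pad <- ceiling(5 * wpx)
    r0 <- max(1L, min(rr) - pad); r1 <- min(nrow(L), max(rr) + pad)
    c0 <- max(1L, min(cc) - pad); c1 <- min(ncol(L), max(cc) + pad)
    win <- dna_image[r0:r1, c0:c1, drop = FALSE]
    thr <- otsu_threshold(win)
    fg <- win > thr
    # the halo is annular (edge-bright): fill enclosed holes so the cloud's
    # outer envelope is measured, not the bright rim alone
    holes <- cpp_label_components(!fg)
    border_ids <- unique(c(holes[1, ], holes[nrow(holes), ],
                           holes[, 1], holes[, ncol(holes)]))
    fg <- fg | (holes > 0L & !(holes %in% border_ids))
    dim(fg) <- dim(win)
    comp <- cpp_label_components(fg)
    # component with the largest overlap with the cell mask
    cell_px <- cbind(rr - r0 + 1L, cc - c0 + 1L)
    over <- comp[cell_px]
    over <- over[over > 0L]
    if (!length(over)) {
      message(sprintf("label %d: no DNA signal overlapping the cell; skipped",
                      lab))
      next
    }
    target <- as.integer(names(which.max(table(over))))
    didx <- which(comp == target)
    drr <- (didx - 1L) %% nrow(comp) + 1L
    dcc <- (didx - 1L) %/% nrow(comp) + 1L
    ax <- long_axis(drr, dcc, px)
    sub <- matrix(0, nrow(comp), ncol(comp))
    sub[cbind(drr, dcc)] <- 1
    dna_w <- mean(width_profile(sub, ax, px))
    ratio <- dna_w / cells$width_um[i]
    out[[i]] <- data.frame(label = lab, cyto_width_um = cells$width_um[i],
                           dna_width_um = dna_w, ratio = ratio,
                           expanded = ratio >= cutoff)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(label = integer(), cyto_width_um = numeric(),
                      dna_width_um = numeric(), ratio = numeric(),
                      expanded = logical()))
  do.call(rbind, out)
}

#' Fraction of halo cells across replicate experiments
#'
#' Per-replicate fraction of cells called expanded; the reported value is
#' the mean over replicates and the SEM the SD over replicates divided by
#' the square root of the number of replicates. Empty replicates are
#' excluded with a message.
#'
#' @param calls_by_replicate List of [detect_halo()] data.frames (or logical
#'   vectors of expanded flags), one per replicate.
#' @return List `fraction`, `sem`, `per_replicate`, `n_replicates`.
#' @export
halo_fraction <- function(calls_by_replicate) {
  stopifnot(is.list(calls_by_replicate), length(calls_by_replicate) >= 1L)
  fr <- numeric(0)
  for (i in seq_along(calls_by_replicate)) {
    rep_i <- calls_by_replicate[[i]]
    flags <- if (is.data.frame(rep_i)) rep_i$expanded else as.logical(rep_i)
    if (!length(flags)) {
      message(sprintf("replicate %d is empty; excluded", i))
      next
    }
    fr <- c(fr, mean(flags))
  }
  if (!length(fr)) stop("all replicates empty", call. = FALSE)
  sem <- if (length(fr) > 1L) stats::sd(fr) / sqrt(length(fr)) else 0
  list(fraction = mean(fr), sem = sem, per_replicate = fr,
       n_replicates = length(fr))
}
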