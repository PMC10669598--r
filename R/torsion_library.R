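## Bounded glycosidic-torsion probability histograms and corpus
## curation. Histograms are bell-shaped distributions over 1-degree
## bins of (-180, 180], strictly zero outside a circular window of
## +/- halfwidth (default 30 degrees) around a center; the semi-rigid
## docking regime samples glycosidic torsions from these.

#' Build a bounded torsional probability histogram
#'
#' The default raised-cosine bell has weight proportional to
#' cos^2(pi * d / (2 * halfwidth)) at circular distance d from the
#' center, exactly zero for d > halfwidth; `truncated-gaussian` uses
#' sd = halfwidth / 2 truncated at the window; `flat` is uniform over
#' the window (at halfwidth 180 this is the fully flexible regime's
#' implicit uniform prior).
#'
#' @param center degrees in (-180, 180].
#' @param halfwidth degrees, 0 < halfwidth <= 180.
#' @param bin_width degrees; must divide 360.
#' @param shape "raised-cosine", "truncated-gaussian" or "flat".
#' @return object of class `torsion_histogram` with fields center,
#'   halfwidth, bin_width, shape, angles (bin centers) and weights
#'   (normalized probabilities).
#' @export
build_histogram <- function(center, halfwidth = 30, bin_width = 1,
                            shape = c("raised-cosine", "truncated-gaussian",
                                      "flat")) {
  shape <- match.arg(shape)
  if (!(halfwidth > 0 && halfwidth <= 180))
    stop("halfwidth must be in (0, 180]")
  nb <- 360 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide 360")
  nb <- round(nb)
  center <- wrap_angle(center)
  angles <- -180 + (seq_len(nb) - 0.5) * bin_width
  d <- circular_dist(angles, center)
  w <- switch(shape,
    "raised-cosine" = ifelse(d <= halfwidth,
                             cos(pi * d / (2 * halfwidth))^2, 0),
    "truncated-gaussian" = ifelse(d <= halfwidth,
                                  exp(-d^2 / (2 * (halfwidth / 2)^2)), 0),
    "flat" = as.numeric(d <= halfwidth))
  if (sum(w) <= 0) stop("histogram has empty support")
  structure(list(center = center, halfwidth = halfwidth,
                 bin_width = bin_width, shape = shape,
                 angles = angles, weights = w / sum(w)),
            class = "torsion_histogram")
}

#' @export
print.torsion_histogram <- function(x, ...) {
  cat(sprintf("torsion_histogram: center %.1f, halfwidth %.1f, %s, %d bins\n",
              x$center, x$halfwidth, x$shape, length(x$weights)))
  invisible(x)
}

## TRUE where an angle is inside the histogram support (circularly)
hist_supports <- function(hist, angle) {
  circular_dist(angle, hist$center) <= hist$halfwidth + 1e-9
}

#' Sample torsion angles from a bounded histogram
#'
#' Inverse-CDF sampling over bins with uniform jitter within the bin,
#' clamped to the circular support. Reproducible under `set.seed()`.
#'
#' @param hist a `torsion_histogram`.
#' @param n number of samples.
#' @return angles in degrees, all inside the support.
#' @export
sample_torsion <- function(hist, n = 1) {
  cum <- cumsum(hist$weights)
  u <- stats::runif(n)
  k <- findInterval(u, cum) + 1
  k[k > length(hist$angles)] <- length(hist$angles)
  ang <- hist$angles[k] + (stats::runif(n) - 0.5) * hist$bin_width
  ang <- wrap_angle(ang)
  ## clamp into the support window (bin jitter can cross the edge)
  d <- wrap_angle(ang - hist$center)
  d[d > hist$halfwidth] <- hist$halfwidth
  d[d < -hist$halfwidth] <- -hist$halfwidth
  wrap_angle(hist$center + d)
}

## ---------------------------------------------------------------------
## corpus curation
## ---------------------------------------------------------------------

#' Curate glycosidic torsion observations from a chain corpus
#'
#' Extracts one (Phi, Psi) observation per linkage, grouped into the
#' UA->GlcN and GlcN->UA classes, and summarizes each class with
#' circular means, circular standard deviations and kernel-density
#' modes (reported as candidate histogram centers, not asserted).
#'
#' @param chains list of `gag_chain`; names are used as source ids.
#' @param kde_bw kernel bandwidth in degrees for mode detection.
#' @return list(observations = data.frame(source_id, linkage_class,
#'   phi, psi), summary = data.frame per class, modes = nested list of
#'   candidate (phi, psi) modes per class).
#' @export
curate_torsions <- function(chains, kde_bw = 10) {
  if (length(chains) == 0)
    return(list(observations = data.frame(source_id = character(),
                                          linkage_class = character(),
                                          phi = numeric(), psi = numeric()),
                summary = data.frame(), modes = list()))
  ids <- names(chains)
  if (is.null(ids)) ids <- sprintf("chain%03d", seq_along(chains))
  obs <- do.call(rbind, lapply(seq_along(chains), function(k) {
    lk <- chains[[k]]$linkages
    if (nrow(lk) == 0) return(NULL)
    data.frame(source_id = ids[k], linkage_class = lk$class,
               phi = lk$phi, psi = lk$psi)
  }))
  classes <- sort(unique(obs$linkage_class))
  summ <- do.call(rbind, lapply(classes, function(cl) {
    s <- obs[obs$linkage_class == cl, ]
    data.frame(linkage_class = cl, n = nrow(s),
               phi_mean = circular_mean(s$phi), phi_sd = circular_sd(s$phi),
               psi_mean = circular_mean(s$psi), psi_sd = circular_sd(s$psi))
  }))
  modes <- lapply(classes, function(cl) {
    s <- obs[obs$linkage_class == cl, ]
    list(phi = circular_modes(s$phi, kde_bw),
         psi = circular_modes(s$psi, kde_bw))
  })
  names(modes) <- classes
  list(observations = obs, summary = summ, modes = modes)
}

## kernel-density modes of circular data: replicate at +/-360 so the
## wrap point is smooth, then keep local maxima inside (-180, 180]
circular_modes <- function(x, bw = 10, min_height = 0.1) {
  if (length(x) < 2) return(wrap_angle(x))
  d <- stats::density(c(x - 360, x, x + 360), bw = bw, n = 2048)
  keep <- d$x > -180 & d$x <= 180
  xs <- d$x[keep]; ys <- d$y[keep]
  n <- length(ys)
  loc <- which(ys > c(ys[-1], -Inf) & ys >= c(-Inf, ys[-n]))
  loc <- loc[ys[loc] >= min_height * max(ys)]
  xs[loc][order(ys[loc], decreasing = TRUE)]
}

#' Export torsion observations to CSV
#' @param curation result of [curate_torsions()].
#' @param path output path.
#' @export
write_torsion_csv <- function(curation, path) {
  utils::write.csv(curation$observations, path, row.names = FALSE)
  invisible(path)
}

#' Ramachandran-style scatter plot of curated torsions
#' @param curation result of [curate_torsions()].
#' @param file optional PNG path; if NULL plots to the active device.
#' @export
plot_torsion_map <- function(curation, file = NULL) {
  obs <- curation$observations
  if (!is.null(file)) grDevices::png(file, width = 700, height = 700)
  cls <- factor(obs$linkage_class)
  graphics::plot(obs$phi, obs$psi, col = as.integer(cls), pch = 19,
                 xlim = c(-180, 180), ylim = c(-180, 180),
                 xlab = expression(Phi ~ "(deg)"),
                 ylab = expression(Psi ~ "(deg)"),
                 main = "Glycosidic torsion map")
  graphics::legend("topright", legend = levels(cls),
                   col = seq_along(levels(cls)), pch = 19)
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}

## ---------------------------------------------------------------------
## distribution files
## ---------------------------------------------------------------------

#' Write a torsion histogram to a plain-text distribution file
#'
#' Documented format: a header (`linkage`, `center`, `halfwidth`,
#' `bin_width`, `shape` lines) followed by one `angle weight` pair per
#' bin. Round-trips exactly to 1e-9.
#'
#' @param hist a `torsion_histogram`.
#' @param linkage_id identifier written in the header.
#' @param path output path.
#' @export
write_distribution_file <- function(hist, linkage_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# glycodock torsion distribution v1",
               paste("linkage", linkage_id),
               sprintf("center %.10g", hist$center),
               sprintf("halfwidth %.10g", hist$halfwidth),
               sprintf("bin_width %.10g", hist$bin_width),
               paste("shape", hist$shape)), con)
  writeLines(sprintf("%.6f %.17g", hist$angles, hist$weights), con)
  invisible(path)
}

#' Read a torsion distribution file
#' @param path file path.
#' @return a `torsion_histogram` (linkage id in attribute `linkage_id`).
#' @export
read_distribution_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hdr <- list()
  data_start <- NA
  for (k in seq_along(lines)) {
    parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (parts[1] %in% c("linkage", "center", "halfwidth", "bin_width",
                        "shape")) {
      hdr[[parts[1]]] <- parts[2]
    } else {
      data_start <- k
      break
    }
  }
  need <- c("linkage", "center", "halfwidth", "bin_width", "shape")
  if (!all(need %in% names(hdr)) || is.na(data_start))
    stop("malformed distribution file: incomplete header in ", path)
  rows <- lines[data_start:length(lines)]
  mat <- matrix(NA_real_, nrow = length(rows), ncol = 2)
  for (k in seq_along(rows)) {
    parts <- suppressWarnings(as.numeric(strsplit(trimws(rows[k]),
                                                  "\\s+")[[1]]))
    if (length(parts) != 2 || any(is.na(parts)))
      stop("malformed distribution file line ", data_start + k - 1,
           " in ", path)
    mat[k, ] <- parts
  }
  if (abs(sum(mat[, 2]) - 1) > 1e-6)
    stop("distribution file is not normalized (sum = ", sum(mat[, 2]), ")")
  h <- structure(list(center = as.numeric(hdr$center),
                      halfwidth = as.numeric(hdr$halfwidth),
                      bin_width = as.numeric(hdr$bin_width),
                      shape = hdr$shape,
                      angles = mat[, 1], weights = mat[, 2]),
                 class = "torsion_histogram")
  attr(h, "linkage_id") <- hdr$linkage
  h
}
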