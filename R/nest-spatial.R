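## Nest neighborhood statistics: nests modeled as disks of equivalent area;
## mean neighbor sizes within annuli around each target nest, split by
## target size, compared against a within-field area-permutation null with
## 5th/95th percentile envelopes.

.checkNestTable <- function(fields) {
  need <- c("field_id", "x_um", "y_um", "area_um2")
  if (!is.data.frame(fields) || !all(need %in% colnames(fields)))
    stop("nest table must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (any(!is.finite(fields$x_um)) || any(!is.finite(fields$y_um)))
    stop("coordinates must be finite")
  if (any(fields$area_um2 <= 0)) stop("areas must be positive")
  invisible(fields)
}

#' Radius of the disk with a nest's area
#'
#' @param area nest area(s) in um^2 (> 0).
#' @return equivalent radius in um: \code{sqrt(area/pi)}.
#' @examples
#' equivalentRadius(1385)  # ~21 um, a typical nest cross-section
#' @export
equivalentRadius <- function(area) {
  if (any(area <= 0)) stop("area must be positive")
  sqrt(area / pi)
}

#' Split nests into small and large at a radius threshold
#'
#' @param fields nest table (field_id, x_um, y_um, area_um2).
#' @param split_radius size split in um (default 20).
#' @return character vector ("small"/"large") per nest; radius < split is
#'   small, radius > split large; exact ties go to "large" and are counted
#'   in the \code{n_ties} attribute.
#' @export
classifyNests <- function(fields, split_radius = 20) {
  .checkNestTable(fields)
  r <- equivalentRadius(fields$area_um2)
  out <- ifelse(r < split_radius, "small", "large")
  attr(out, "n_ties") <- sum(r == split_radius)
  out
}

#' Mean equivalent radius of neighbors within an annulus of one nest
#'
#' Neighbors are the other nests of the same field whose centers lie within
#' \code{annulus_width} of the target's perimeter, i.e. within
#' \code{target radius + annulus_width} of the target's center
#' (\code{rule = "center"}); \code{rule = "edge"} additionally credits the
#' neighbor its own radius (edge-to-edge distance).
#'
#' @param target row index of the target nest within \code{field}.
#' @param field single-field nest table.
#' @param annulus_width annulus extent beyond the target perimeter (um).
#' @param rule neighbor-inclusion rule.
#' @return mean neighbor equivalent radius, or NA if the target has no
#'   neighbor in range (such targets are excluded from histograms).
#' @export
meanNeighborSize <- function(target, field, annulus_width = 45,
                             rule = c("center", "edge")) {
  rule <- match.arg(rule)
  .checkNestTable(field)
  stopifnot(length(unique(field$field_id)) == 1, target >= 1,
            target <= nrow(field))
  r <- equivalentRadius(field$area_um2)
  d <- sqrt((field$x_um - field$x_um[target])^2 +
            (field$y_um - field$y_um[target])^2)
  lim <- r[target] + annulus_width + if (rule == "edge") r else 0
  nb <- which(d <= lim & seq_len(nrow(field)) != target)
  if (!length(nb)) return(NA_real_)
  mean(r[nb])
}

## all-target mean neighbor sizes for one field, vectorized over targets
.fieldNeighborMeans <- function(x, y, r, annulus_width, rule = "center") {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  lim <- matrix(r + annulus_width, n, n)        # row = target
  if (rule == "edge") lim <- lim + matrix(r, n, n, byrow = TRUE)
  A <- D <= lim
  diag(A) <- FALSE
  cnt <- rowSums(A)
  means <- as.vector(A %*% r) / cnt
  means[cnt == 0] <- NA_real_
  means
}

#' Histograms of mean neighbor sizes for small- and large-target nests
#'
#' Fields with fewer than \code{min_nests} nests are dropped. Per size
#' class of the target (radius below/above \code{split_radius}), the
#' per-target mean neighbor radii are binned on fixed edges shared with the
#' permutation null.
#'
#' @param fields nest table covering one or more fields.
#' @param annulus_width annulus extent (um), default 45.
#' @param split_radius target size split (um), default 20.
#' @param min_nests minimum nests per field (default 10).
#' @param bin_width histogram bin width (um), default 5.
#' @param max_radius upper edge of the last bin (um).
#' @param rule neighbor-inclusion rule (see \code{\link{meanNeighborSize}}).
#' @return list with \code{breaks}, count vectors \code{small} and
#'   \code{large}, the per-target values, and the fields used.
#' @export
neighborSizeHistograms <- function(fields, annulus_width = 45,
                                   split_radius = 20, min_nests = 10L,
                                   bin_width = 5, max_radius = 100,
                                   rule = c("center", "edge")) {
  rule <- match.arg(rule)
  .checkNestTable(fields)
  keep <- names(which(table(fields$field_id) >= min_nests))
  if (!length(keep)) stop("no field has at least ", min_nests, " nests")
  fields <- fields[fields$field_id %in% keep, , drop = FALSE]
  breaks <- seq(0, max_radius, by = bin_width)
  vals <- list(small = numeric(), large = numeric())
  for (f in keep) {
    sub <- fields[fields$field_id == f, , drop = FALSE]
    r <- equivalentRadius(sub$area_um2)
    m <- .fieldNeighborMeans(sub$x_um, sub$y_um, r, annulus_width, rule)
    cls <- ifelse(r < split_radius, "small", "large")
    for (k in c("small", "large"))
      vals[[k]] <- c(vals[[k]], m[cls == k & !is.na(m)])
  }
  counts <- lapply(vals, function(v)
    graphics::hist(pmin(v, max_radius - 1e-9), breaks = breaks,
                   plot = FALSE)$counts)
  list(breaks = breaks, small = counts$small, large = counts$large,
       values = vals, fields_used = keep)
}

#' Permutation envelope for the neighbor-size histograms
#'
#' Nest areas are randomly permuted within each field (positions held
#' constant) \code{n_perm} times; the small/large histograms are recomputed
#' each time on the same bin edges, and the per-bin 5th and 95th
#' percentiles form the envelope. Observed bins outside the envelope are
#' flagged.
#'
#' @param fields nest table.
#' @param n_perm number of permutations (>= 100; default 5000).
#' @param seed optional integer seed (fixed seed, identical envelope).
#' @param annulus_width,split_radius,min_nests,bin_width,max_radius,rule
#'   passed to \code{\link{neighborSizeHistograms}}; the observed and
#'   permuted statistics share them.
#' @param probs envelope percentiles (default 5th and 95th).
#' @return list with the observed histograms (\code{observed}), per-class
#'   envelope vectors \code{lo}/\code{hi} per bin, logical flag vectors
#'   \code{flags} (exact Monte Carlo rank test with randomized tie-breaking,
#'   calibrated to the nominal two-sided level even though counts are
#'   discrete), \code{flags_strict} (plain outside-the-envelope comparison,
#'   conservative under ties), two scalar association tests --
#'   \code{asymmetry} (difference of class mean neighbor sizes) and
#'   \code{size_proximity} (correlation of nest radius with exponential
#'   crowding load, the targeted alternative for short-range growth
#'   inhibition) -- each with a permutation p-value, plus \code{n_perm}
#'   and \code{seed}.
#' @export
permutationEnvelope <- function(fields, n_perm = 5000L, seed = NULL,
                                annulus_width = 45, split_radius = 20,
                                min_nests = 10L, bin_width = 5,
                                max_radius = 100,
                                rule = c("center", "edge"),
                                probs = c(0.05, 0.95)) {
  rule <- match.arg(rule)
  if (n_perm < 100) stop("n_perm < 100 gives unusable envelopes; refused")
  .checkNestTable(fields)
  if (!is.null(seed)) set.seed(seed)
  obs <- neighborSizeHistograms(fields, annulus_width, split_radius,
                                min_nests, bin_width, max_radius, rule)
  fields <- fields[fields$field_id %in% obs$fields_used, , drop = FALSE]
  byf <- split(fields, fields$field_id)
  geo <- lapply(byf, function(sub)
    list(x = sub$x_um, y = sub$y_um, area = sub$area_um2))
  breaks <- obs$breaks
  nb <- length(breaks) - 1L
  perm_small <- matrix(0L, n_perm, nb)
  perm_large <- matrix(0L, n_perm, nb)
  perm_asym <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    vs <- numeric(); vl <- numeric()
    for (g in geo) {
      a <- g$area[sample.int(length(g$area))]
      r <- sqrt(a / pi)
      m <- .fieldNeighborMeans(g$x, g$y, r, annulus_width, rule)
      ok <- !is.na(m)
      sm <- r < split_radius
      vs <- c(vs, m[ok & sm]); vl <- c(vl, m[ok & !sm])
    }
    perm_small[p, ] <- graphics::hist(pmin(vs, max_radius - 1e-9),
                                      breaks = breaks, plot = FALSE)$counts
    perm_large[p, ] <- graphics::hist(pmin(vl, max_radius - 1e-9),
                                      breaks = breaks, plot = FALSE)$counts
    perm_asym[p] <- mean(vl) - mean(vs)
  }
  ## size-proximity correlation: nest radius vs exponential crowding load
  ## (range = annulus width); negative under short-range growth inhibition
  loadCorr <- function(radii_by_field) {
    num <- 0; den <- 0
    for (fi in seq_along(geo)) {
      g <- geo[[fi]]; r <- radii_by_field[[fi]]
      D <- as.matrix(stats::dist(cbind(g$x, g$y)))
      diag(D) <- Inf
      L <- rowSums(exp(-D / annulus_width))
      if (stats::sd(r) > 0 && stats::sd(L) > 0) {
        num <- num + stats::cor(r, L) * length(r)
        den <- den + length(r)
      }
    }
    if (den == 0) NA_real_ else num / den
  }
  obs_corr <- loadCorr(lapply(geo, function(g) sqrt(g$area / pi)))
  perm_corr <- vapply(seq_len(min(n_perm, 1000L)), function(p) {
    loadCorr(lapply(geo, function(g)
      sqrt(g$area[sample.int(length(g$area))] / pi)))
  }, numeric(1))
  p_corr <- (1 + sum(abs(perm_corr) >= abs(obs_corr))) /
    (length(perm_corr) + 1)
  env <- function(M) apply(M, 2, stats::quantile, probs = probs, names = FALSE)
  es <- env(perm_small); el <- env(perm_large)
  ## flags: exact Monte Carlo rank test. Histogram counts are integers, so
  ## a strict outside-the-envelope rule is conservative under ties; ranking
  ## the observed count among the permuted ones with uniformly randomized
  ## tie-breaking restores the exact two-sided level
  ## (probs[1] + 1 - probs[2], i.e. 10% at the defaults) in every bin.
  m_lo <- floor(probs[1] * (n_perm + 1))
  m_hi <- floor((1 - probs[2]) * (n_perm + 1))
  rankFlag <- function(o, M) {
    nbins <- length(o)
    hi <- lo <- logical(nbins)
    for (b in seq_len(nbins)) {
      vj <- M[, b] + stats::runif(n_perm)
      oj <- o[b] + stats::runif(1)
      hi[b] <- sum(vj > oj) < m_hi
      lo[b] <- sum(vj < oj) < m_lo
    }
    hi | lo
  }
  strictFlag <- function(o, e) o < e[1, ] | o > e[2, ]
  ## scalar class-asymmetry statistic: difference of the class mean
  ## neighbor sizes, observed vs its permutation distribution (two-sided
  ## rank p-value). Size-position inhibition shows up here as large targets
  ## having smaller neighbors than small targets.
  obs_asym <- mean(obs$values$large) - mean(obs$values$small)
  ok <- is.finite(perm_asym)
  p_asym <- if (is.finite(obs_asym) && sum(ok) >= 100)
    (1 + sum(abs(perm_asym[ok] - mean(perm_asym[ok])) >=
               abs(obs_asym - mean(perm_asym[ok])))) / (sum(ok) + 1)
  else NA_real_
  list(observed = obs, breaks = breaks,
       lo = list(small = es[1, ], large = el[1, ]),
       hi = list(small = es[2, ], large = el[2, ]),
       flags = list(small = rankFlag(obs$small, perm_small),
                    large = rankFlag(obs$large, perm_large)),
       flags_strict = list(small = strictFlag(obs$small, es),
                           large = strictFlag(obs$large, el)),
       asymmetry = list(observed = obs_asym, p_value = p_asym,
                        perm_mean = mean(perm_asym[ok])),
       size_proximity = list(correlation = obs_corr, p_value = p_corr),
       n_perm = n_perm, seed = seed)
}

#' Median nearest-neighbor spacing between nests
#'
#' Spacing is operationalized as the nearest-neighbor center-to-center
#' distance of each nest within its field; the median is taken over all
#' nests of all fields with at least two nests.
#'
#' @param fields nest table.
#' @return median spacing in um.
#' @export
medianNestSpacing <- function(fields) {
  .checkNestTable(fields)
  nn <- unlist(lapply(split(fields, fields$field_id), function(sub) {
    if (nrow(sub) < 2) return(numeric())
    D <- as.matrix(stats::dist(cbind(sub$x_um, sub$y_um)))
    diag(D) <- Inf
    apply(D, 1, min)
  }))
  stats::median(nn)
}

#' Cells per nevus from volumetric density
#'
#' Product of a measured cell density per nest volume, the average nest
#' volume, and the average number of nests per nevus. At the measured
#' values (14.4 cells per 10^4 um^3, 38792 um^3 per nest, 12 nests) this is
#' 670.3 cells per nevus.
#'
#' @param cells_per_1e4_um3 cells per 10^4 um^3 of nest.
#' @param nest_volume_um3 average nest volume (um^3).
#' @param nests_per_nevus average nests per nevus.
#' @return estimated cells per nevus.
#' @examples
#' cellsPerNevusVolumetric()  # 670.3
#' @export
cellsPerNevusVolumetric <- function(cells_per_1e4_um3 = 14.4,
                                    nest_volume_um3 = 38792,
                                    nests_per_nevus = 12) {
  stopifnot(cells_per_1e4_um3 > 0, nest_volume_um3 > 0, nests_per_nevus > 0)
  cells_per_1e4_um3 * nest_volume_um3 / 1e4 * nests_per_nevus
}

#' Disk area in mm^2 from a radius in um
#'
#' @param radius_um radius in micrometers (> 0 allowed to be vector).
#' @return area in mm^2: \code{pi * r^2 * 1e-6}.
#' @examples
#' diskAreaMm2(76.8)  # ~0.019 mm^2, the median mouse nevus
#' @export
diskAreaMm2 <- function(radius_um) {
  if (any(radius_um < 0)) stop("radius must be non-negative")
  pi * radius_um^2 * 1e-6
}
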