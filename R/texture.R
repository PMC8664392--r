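#' Quantize a parametric map to gray levels
#'
#' Uniformly bins valid cells between their min and max into `n_levels`
#' levels (1..Ng). A constant map maps to level 1 everywhere. Invalid cells
#' stay NA and are skipped by the co-occurrence counting.
#'
#' @param map A `parametric_map`, or a plain numeric matrix (NAs invalid).
#' @param n_levels Number of gray levels Ng.
#' @param range Optional fixed (min, max) to bin against instead of the
#'   map's own valid range (used for map-global quantization of local
#'   windows).
#' @return An object of class `quantized_map`: `levels` (integer matrix with
#'   NA for invalid cells), `n_levels`, `source_range`.
#' @export
quantize_map <- function(map, n_levels = 16L, range = NULL) {
  if (inherits(map, "parametric_map")) {
    v <- map$values
    v[!map$valid_mask] <- NA_real_
  } else {
    v <- as.matrix(map)
  }
  if (sum(is.finite(v)) < 1L) stop("map has no valid cells to quantize")
  if (is.null(range)) range <- c(min(v, na.rm = TRUE), max(v, na.rm = TRUE))
  span <- range[2] - range[1]
  lev <- matrix(NA_integer_, nrow(v), ncol(v))
  fin <- is.finite(v)
  if (span <= 0) {
    lev[fin] <- 1L
  } else {
    lev[fin] <- pmin(pmax(
      as.integer(floor((v[fin] - range[1]) / span * n_levels)) + 1L, 1L),
      as.integer(n_levels))
  }
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 source_range = range),
            class = "quantized_map")
}

# (row, col) displacement for a GLCM angle at displacement d, image
# convention: 0 deg = lateral neighbour, 90 deg = axial neighbour above.
.angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix at one angle
#'
#' Counts pairs of quantized levels at the given displacement and angle,
#' symmetrically (each pair contributes in both directions), skipping pairs
#' that touch an invalid (NA) cell, and normalizes the matrix to sum 1.
#'
#' @param q A `quantized_map`.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param displacement Pixel displacement (>= 1).
#' @return Ng x Ng numeric matrix summing to 1.
#' @export
compute_glcm <- function(q, angle, displacement = 1L) {
  lev <- q$levels
  ng <- q$n_levels
  off <- .angle_offset(angle, as.integer(displacement))
  nr <- nrow(lev); nc <- ncol(lev)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (length(r1) < 1L || length(c1) < 1L) {
    stop("displacement exceeds map size for this angle")
  }
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + off[1], c1 + off[2], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no valid pixel pairs at this displacement/angle")
  a <- a[keep]; b <- b[keep]
  counts <- tabulate(c((a - 1L) * ng + b, (b - 1L) * ng + a), nbins = ng * ng)
  m <- matrix(counts, ng, ng, byrow = TRUE)
  m / sum(m)
}

#' GLCM texture features: contrast, correlation, energy, homogeneity
#'
#' CON = sum (i-j)^2 p(i,j); COR = sum (i-mu_i)(j-mu_j) p(i,j) / (s_i s_j);
#' ENE = sum p^2; HOM = sum p / (1 + |i-j|). When either marginal standard
#' deviation is zero COR is defined as 0.
#'
#' @param glcm Normalized co-occurrence matrix (sums to 1).
#' @return Named numeric vector `con`, `cor`, `ene`, `hom`.
#' @export
glcm_features <- function(glcm) {
  if (abs(sum(glcm) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  ng <- nrow(glcm)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_ <- rowSums(glcm)
  mu_i <- sum(seq_len(ng) * pi_)
  mu_j <- sum(seq_len(ng) * colSums(glcm))
  s_i <- sqrt(sum((seq_len(ng) - mu_i)^2 * pi_))
  s_j <- sqrt(sum((seq_len(ng) - mu_j)^2 * colSums(glcm)))
  con <- sum((i - j)^2 * glcm)
  cor <- if (s_i > 0 && s_j > 0) {
    sum((i - mu_i) * (j - mu_j) * glcm) / (s_i * s_j)
  } else 0
  c(con = con, cor = cor, ene = sum(glcm^2),
    hom = sum(glcm / (1 + abs(i - j))))
}

#' Angle-averaged GLCM texture features of a whole map
#'
#' Quantizes the map once, computes the GLCM at each of the four angles and
#' averages each feature over angles. Angles with no valid pixel pairs are
#' skipped with a warning.
#'
#' @param map A `parametric_map` or numeric matrix.
#' @param n_levels Gray levels.
#' @param displacement Pixel displacement.
#' @param angles Angles in degrees.
#' @return Named numeric vector `con`, `cor`, `ene`, `hom`.
#' @export
texture_of_map <- function(map, n_levels = 16L, displacement = 1L,
                           angles = c(0, 45, 90, 135)) {
  q <- quantize_map(map, n_levels)
  texture_of_quantized(q, displacement, angles)
}

#' @rdname texture_of_map
#' @param q A `quantized_map` (already binned).
#' @export
texture_of_quantized <- function(q, displacement = 1L,
                                 angles = c(0, 45, 90, 135)) {
  acc <- NULL
  n_ok <- 0L
  for (ang in angles) {
    feats <- tryCatch(
      glcm_features(compute_glcm(q, ang, displacement)),
      error = function(e) NULL)
    if (is.null(feats)) next
    acc <- if (is.null(acc)) feats else acc + feats
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) stop("no angle produced valid pixel pairs")
  if (n_ok < length(angles)) {
    warning(sprintf("%d of %d angles had no valid pairs and were skipped",
                    length(angles) - n_ok, length(angles)))
  }
  acc / n_ok
}

#' Regenerated local texture maps of a parametric map
#'
#' For every grid cell, GLCM features are computed over the odd-sized
#' neighbourhood window centred there (clipped at the map edge), using the
#' map-global quantization so local windows share one gray scale. Cells
#' whose window has no valid pixel pair at any angle are invalid. Returns
#' one texture map per GLCM feature.
#'
#' @param map A `parametric_map`.
#' @param n_levels Gray levels.
#' @param displacement Pixel displacement.
#' @param neighborhood Odd window size in grid cells (>= 3).
#' @param angles Angles in degrees.
#' @return Named list of 4 `parametric_map`s (`con`, `cor`, `ene`, `hom`),
#'   each named `<param>-<FEATURE>`.
#' @export
texture_map_of <- function(map, n_levels = 16L, displacement = 1L,
                           neighborhood = 5L, angles = c(0, 45, 90, 135)) {
  if (neighborhood %% 2L != 1L || neighborhood < 3L) {
    stop("neighborhood must be odd and >= 3")
  }
  nr <- nrow(map$values); nc <- ncol(map$values)
  if (neighborhood > nr && neighborhood > nc) {
    stop("neighborhood larger than the map")
  }
  q <- quantize_map(map, n_levels)
  h <- (neighborhood - 1L) %/% 2L
  out <- lapply(1:4, function(i) matrix(NA_real_, nr, nc))
  names(out) <- c("con", "cor", "ene", "hom")
  valid <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rows <- max(1L, i - h):min(nr, i + h)
      cols <- max(1L, j - h):min(nc, j + h)
      sub <- structure(list(levels = q$levels[rows, cols, drop = FALSE],
                            n_levels = q$n_levels,
                            source_range = q$source_range),
                       class = "quantized_map")
      feats <- tryCatch(
        suppressWarnings(texture_of_quantized(sub, displacement, angles)),
        error = function(e) NULL)
      if (is.null(feats)) next
      valid[i, j] <- TRUE
      for (nm in names(out)) out[[nm]][i, j] <- feats[[nm]]
    }
  }
  if (!any(valid)) stop("no cell produced a valid local texture window")
  base <- map$parameter_name
  maps <- lapply(names(out), function(nm) {
    parametric_map(paste0(base, "-", toupper(nm)), out[[nm]], valid)
  })
  names(maps) <- names(out)
  maps
}

#' Texture-derivative features from regenerated texture maps
#'
#' Third-order features: applies the angle-averaged GLCM analysis to each of
#' the 16 texture maps (base parameters MBF, SI, ASD, AAC x CON, COR, ENE,
#' HOM; the SS and SAS texture maps are not used), quantizing each texture
#' map on its own min-max. Yields 64 named scalars `PARAM-TEX1-TEX2`, e.g.
#' `SI-COR-CON`.
#'
#' @param texture_maps Named list: for each eligible base parameter, the list
#'   of 4 texture maps from [texture_map_of()].
#' @param n_levels Gray levels for the second GLCM pass.
#' @param displacement Pixel displacement.
#' @param angles Angles in degrees.
#' @return Named numeric vector of length 64 (NA where a second-pass GLCM
#'   was not computable).
#' @export
texture_derivative <- function(texture_maps, n_levels = 16L, displacement = 1L,
                               angles = c(0, 45, 90, 135)) {
  eligible <- c("MBF", "SI", "ASD", "AAC")
  feats <- c("CON", "COR", "ENE", "HOM")
  missing <- setdiff(eligible, names(texture_maps))
  if (length(missing) > 0L) {
    stop("missing texture maps for: ", paste(missing, collapse = ", "))
  }
  out <- c()
  for (p in eligible) {
    tmaps <- texture_maps[[p]]
    for (t1 in feats) {
      tm <- tmaps[[tolower(t1)]]
      if (is.null(tm)) stop("missing texture map ", p, "-", t1)
      second <- tryCatch(
        suppressWarnings(texture_of_map(tm, n_levels, displacement, angles)),
        error = function(e) rep(NA_real_, 4))
      names(second) <- feats
      nm <- paste(p, t1, feats, sep = "-")
      v <- as.numeric(second)
      names(v) <- nm
      out <- c(out, v)
    }
  }
  out
}
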