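#' Ordered per-ring cell trait sequences
#'
#' A tracheidogram is the ordered sequence of tracheid traits along one radial
#' file across a ring, from the first-formed (innermost) cell outward. Radial
#' diameter \code{D} and wall thickness \code{CWT} are in micrometres.
#'
#' @param D,CWT numeric vectors of equal length (\eqn{\mu m}), all positive
#'   with \code{CWT/D < 0.5} (positive lumen).
#' @param tree_id,year optional identifiers carried along.
#' @return an object of class \code{"tracheidogram"}: list with \code{D},
#'   \code{CWT}, \code{n_cells}, \code{tree_id}, \code{year}.
#' @export
tracheidogram <- function(D, CWT, tree_id = NULL, year = NULL) {
  if (length(D) < 1L || length(D) != length(CWT))
    stop("D and CWT must be non-empty vectors of equal length", call. = FALSE)
  bad <- which(!(D > 0) | !(CWT > 0) | CWT / D >= 0.5)
  if (length(bad))
    stop("invalid cell at position ", bad[1],
         ": need D > 0, CWT > 0 and CWT/D < 0.5 (positive lumen)",
         call. = FALSE)
  structure(list(D = as.numeric(D), CWT = as.numeric(CWT),
                 n_cells = length(D), tree_id = tree_id, year = year),
            class = "tracheidogram")
}

#' @export
print.tracheidogram <- function(x, ...) {
  cat("Tracheidogram", if (!is.null(x$tree_id)) paste0("tree ", x$tree_id),
      if (!is.null(x$year)) paste0("year ", x$year),
      sprintf("(%d cells)\n", x$n_cells))
  cat("  D   (um):", format(round(x$D, 2)), "\n")
  cat("  CWT (um):", format(round(x$CWT, 2)), "\n")
  invisible(x)
}

measurement_cols <- c("tree_id", "year", "row_id", "rank", "D_um", "CWT_um")

#' Read and write per-cell tracheid measurements
#'
#' Delimited text with header columns \code{tree_id}, \code{year},
#' \code{row_id}, \code{rank}, \code{D_um}, \code{CWT_um} (comma by default,
#' any delimiter accepted). \code{rank} is 1-based from the ring's inner
#' border (first-formed cell). Records are validated: positive traits,
#' \code{CWT/D < 0.5}, and consecutive ranks from 1 within each
#' (tree, year, row) group; rows are reordered by rank within groups.
#'
#' @param path file path.
#' @param sep field delimiter (default comma; use \code{"\t"} for TSV).
#' @param cells a measurements data frame.
#' @return \code{read_measurements}: a validated data frame with the six
#'   standard columns; \code{write_measurements}: \code{path}, invisibly.
#' @export
read_measurements <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(measurement_cols, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[measurement_cols]
  validate_measurements(df)
}

#' @rdname read_measurements
#' @export
write_measurements <- function(cells, path, sep = ",") {
  stopifnot(all(measurement_cols %in% names(cells)))
  utils::write.table(cells[measurement_cols], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_measurements
#' @export
validate_measurements <- function(cells) {
  cells <- as.data.frame(cells)
  missing <- setdiff(measurement_cols, names(cells))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!(cells$D_um > 0) | !(cells$CWT_um > 0) |
                 cells$CWT_um / cells$D_um >= 0.5)
  if (length(bad)) {
    r <- cells[bad[1], ]
    stop(sprintf(paste0("invalid record (tree %s, year %s, row %s, rank %s): ",
                        "D = %g, CWT = %g violates D > 0, CWT > 0, ",
                        "CWT/D < 0.5"),
                 r$tree_id, r$year, r$row_id, r$rank, r$D_um, r$CWT_um),
         call. = FALSE)
  }
  key <- interaction(cells$tree_id, cells$year, cells$row_id, drop = TRUE)
  cells <- cells[order(key, cells$rank), , drop = FALSE]
  ok <- tapply(cells$rank, interaction(cells$tree_id, cells$year,
                                       cells$row_id, drop = TRUE),
               function(r) identical(as.integer(r), seq_along(r)))
  if (!all(unlist(ok)))
    stop("ranks must be consecutive from 1 within each (tree, year, row) ",
         "group; offending group: ", names(ok)[which(!unlist(ok))[1]],
         call. = FALSE)
  rownames(cells) <- NULL
  cells
}

#' Normalize a tracheidogram to a standard cell count
#'
#' Stretches or compresses a radial file to \code{target_n} cells without
#' distorting trait values: each input cell is treated as an interval of
#' width \eqn{1/n} on \eqn{[0, 1]} and each output cell of width
#' \eqn{1/target\_n} takes the overlap-weighted average of the input values
#' covering its interval. The rule conserves constant rows exactly, never
#' extrapolates outside the input range, and is the identity when
#' \code{target_n} equals the input length.
#'
#' @param tg a [tracheidogram()] (or numeric vector, treated as one trait).
#' @param target_n desired cell count (>= 1).
#' @return object of the same kind as the input, resampled to
#'   \code{target_n} cells.
#' @export
normalize_row <- function(tg, target_n) {
  if (target_n < 1) stop("target_n must be >= 1", call. = FALSE)
  if (is.numeric(tg)) {
    if (!length(tg)) stop("empty row", call. = FALSE)
    return(resample_overlap(tg, as.integer(target_n)))
  }
  stopifnot(inherits(tg, "tracheidogram"))
  tracheidogram(resample_overlap(tg$D, as.integer(target_n)),
                resample_overlap(tg$CWT, as.integer(target_n)),
                tree_id = tg$tree_id, year = tg$year)
}

# overlap-weighted piecewise-constant resampling of v (length n) to length m
resample_overlap <- function(v, m) {
  n <- length(v)
  if (m == n) return(v)
  out <- numeric(m)
  for (k in seq_len(m)) {
    lo <- (k - 1) / m
    hi <- k / m
    j <- seq.int(max(1L, floor(lo * n) + 1L), min(n, ceiling(hi * n)))
    ov <- pmin(j / n, hi) - pmax((j - 1) / n, lo)
    out[k] <- sum(ov * v[j]) / sum(ov)
  }
  out
}

#' Average several normalized tracheidograms position by position
#'
#' @param tgs list of [tracheidogram()] objects of identical length.
#' @return a \code{tracheidogram} with the positionwise mean of D and CWT.
#' @export
average_rows <- function(tgs) {
  stopifnot(length(tgs) >= 1L)
  ns <- vapply(tgs, function(t) t$n_cells, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all rows must have the same length; got ",
         paste(ns, collapse = ", "), call. = FALSE)
  D <- rowMeans(vapply(tgs, function(t) t$D, numeric(ns[1])))
  CWT <- rowMeans(vapply(tgs, function(t) t$CWT, numeric(ns[1])))
  tracheidogram(D, CWT, tree_id = tgs[[1]]$tree_id, year = tgs[[1]]$year)
}

#' Normalize and average all radial files of a measurement dataset
#'
#' For each ring (tree, year): every radial row is resampled with
#' [normalize_row()] to the ring's mean cell number per row (rounded half
#' up), then rows are averaged positionwise with [average_rows()] to remove
#' random between-row differences. Any number of rows >= 1 per ring is
#' accepted.
#'
#' @param cells validated measurements data frame (see
#'   [read_measurements()]).
#' @return data frame with columns \code{tree_id}, \code{year}, \code{rank},
#'   \code{D_um}, \code{CWT_um} — one averaged tracheidogram per ring.
#' @export
normalize_dataset <- function(cells) {
  cells <- validate_measurements(cells)
  key <- interaction(cells$tree_id, cells$year, drop = TRUE)
  pieces <- lapply(split(cells, key), function(ring) {
    rows <- split(ring, ring$row_id)
    target <- as.integer(floor(mean(vapply(rows, nrow, integer(1))) + 0.5))
    tgs <- lapply(rows, function(r)
      normalize_row(tracheidogram(r$D_um, r$CWT_um), target))
    avg <- average_rows(tgs)
    data.frame(tree_id = ring$tree_id[1], year = ring$year[1],
               rank = seq_len(target), D_um = avg$D, CWT_um = avg$CWT,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$tree_id, out$year, out$rank), , drop = FALSE]
}

#' Slope angle of the CWT/D ratio
#'
#' \eqn{\varphi = \arctan(\mathrm{CWT}/D)} in degrees. On raw traits the
#' angle is confined to a few degrees; on standardized indices (means 1) it
#' spans (0, 90) degrees and its distribution becomes distinctly bimodal.
#'
#' @param ratio positive ratio(s) CWT/D (or CWT_i/D_i).
#' @return angle(s) in degrees, strictly increasing in \code{ratio}.
#' @export
compute_slope_angle <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0))
    stop("ratio must be positive and finite", call. = FALSE)
  atan(ratio) * 180 / pi
}

#' Standardize cell traits to dimensionless indices
#'
#' Divides D and CWT by their mean over the standardization scope (whole
#' dataset by default, or per tree), giving indices \eqn{D_i} and
#' \eqn{\mathrm{CWT}_i} with mean exactly 1, their ratio and the indexed
#' slope angle \eqn{\varphi_i} in degrees.
#'
#' @param cells data frame with at least \code{D_um} and \code{CWT_um}
#'   (e.g. from [read_measurements()] or [normalize_dataset()]).
#' @param scope \code{"dataset"} (default) or \code{"tree"} (means computed
#'   within each \code{tree_id}).
#' @return list with \code{cells} (input plus columns \code{D_i},
#'   \code{CWT_i}, \code{ratio_i}, \code{phi_i}), the scalar (or per-tree)
#'   \code{d_mean} and \code{cwt_mean}, and \code{summary} (see
#'   [dataset_summary()]).
#' @export
standardize_cells <- function(cells, scope = c("dataset", "tree")) {
  scope <- match.arg(scope)
  cells <- as.data.frame(cells)
  if (!nrow(cells)) stop("empty dataset", call. = FALSE)
  stopifnot(all(c("D_um", "CWT_um") %in% names(cells)))
  if (scope == "dataset") {
    d_mean <- mean(cells$D_um)
    cwt_mean <- mean(cells$CWT_um)
    cells$D_i <- cells$D_um / d_mean
    cells$CWT_i <- cells$CWT_um / cwt_mean
  } else {
    stopifnot("tree_id" %in% names(cells))
    dm <- tapply(cells$D_um, cells$tree_id, mean)
    cm <- tapply(cells$CWT_um, cells$tree_id, mean)
    cells$D_i <- cells$D_um / dm[as.character(cells$tree_id)]
    cells$CWT_i <- cells$CWT_um / cm[as.character(cells$tree_id)]
    d_mean <- dm
    cwt_mean <- cm
  }
  cells$ratio_i <- cells$CWT_i / cells$D_i
  cells$phi_i <- compute_slope_angle(cells$ratio_i)
  list(cells = cells, d_mean = d_mean, cwt_mean = cwt_mean,
       summary = dataset_summary(cells))
}

#' Per-trait summary of a measurements dataset
#'
#' Mean, minimum and maximum of D, CWT, CWT/D and the slope angle, plus the
#' standardized counterparts when present, together with tree/ring/cell
#' counts — the layout of a standard sample-depth table.
#'
#' @param cells data frame with \code{D_um}, \code{CWT_um} and optionally
#'   the index columns added by [standardize_cells()].
#' @return data frame with columns \code{trait}, \code{mean}, \code{min},
#'   \code{max}; counts are attached as attributes \code{n_trees},
#'   \code{n_rings}, \code{n_cells}.
#' @export
dataset_summary <- function(cells) {
  traits <- list(D_um = cells$D_um, CWT_um = cells$CWT_um,
                 `CWT/D` = cells$CWT_um / cells$D_um,
                 phi_deg = compute_slope_angle(cells$CWT_um / cells$D_um))
  if ("D_i" %in% names(cells))
    traits <- c(traits, list(D_i = cells$D_i, CWT_i = cells$CWT_i,
                             `CWT_i/D_i` = cells$ratio_i,
                             phi_i_deg = cells$phi_i))
  out <- data.frame(
    trait = names(traits),
    mean = vapply(traits, mean, numeric(1)),
    min = vapply(traits, min, numeric(1)),
    max = vapply(traits, max, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_trees") <- if ("tree_id" %in% names(cells))
    length(unique(cells$tree_id)) else NA_integer_
  attr(out, "n_rings") <- if (all(c("tree_id", "year") %in% names(cells)))
    nrow(unique(cells[c("tree_id", "year")])) else NA_integer_
  attr(out, "n_cells") <- nrow(cells)
  out
}

#' Histogram on fixed-width, left-closed bins
#'
#' Bins values on a regular grid anchored at \code{origin}; membership is
#' left-closed right-open, so a bin labelled by its lower edge \eqn{e}
#' contains \eqn{e \le x < e + width}. Densities are counts normalized to
#' sum 1 (probability per bin). Default widths in this package follow the
#' zonation conventions: 0.01 for CWT/D ratios, 0.5 degrees for raw angles,
#' 1.5 degrees for indexed angles.
#'
#' @param values non-empty numeric vector.
#' @param width bin width (> 0).
#' @param origin grid anchor (default 0).
#' @return object of class \code{"binned_histogram"}: list with
#'   \code{lower_edges}, \code{width}, \code{counts}, \code{densities},
#'   \code{n}.
#' @export
bin_histogram <- function(values, width, origin = 0) {
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  if (!is.finite(width) || width <= 0) stop("width must be > 0", call. = FALSE)
  idx <- floor((values - origin) / width + 1e-12)
  rng <- range(idx)
  counts <- tabulate(idx - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  structure(list(lower_edges = origin + (rng[1]:rng[2]) * width,
                 width = width, counts = counts,
                 densities = counts / sum(counts), n = length(values)),
            class = "binned_histogram")
}

#' @export
print.binned_histogram <- function(x, ...) {
  cat(sprintf("Binned histogram: %d values in %d bins of width %g from %g\n",
              x$n, length(x$counts), x$width, x$lower_edges[1]))
  invisible(x)
}
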