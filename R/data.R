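#' Isotope distribution
#'
#' A set of (m/z, intensity) pairs with the precursor charge state.
#'
#' @param mz strictly increasing m/z values (Thomson).
#' @param intensity nonnegative intensities (arbitrary units); at least
#'   one must be positive.
#' @param charge positive integer charge state.
#' @return an object of class `hdx_isodist`.
#' @export
isotope_distribution <- function(mz, intensity, charge = 1) {
  if (length(mz) != length(intensity) || length(mz) == 0)
    stop("'mz' and 'intensity' must be nonempty and of equal length")
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite m/z or intensity")
  if (any(intensity < 0)) stop("negative intensity")
  if (!any(intensity > 0)) stop("invalid distribution: all intensities zero")
  if (is.unsorted(mz, strictly = TRUE))
    stop("'mz' must be strictly increasing")
  if (length(charge) != 1 || charge < 1 || charge != round(charge))
    stop("'charge' must be a positive integer")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 charge = as.integer(charge)),
            class = "hdx_isodist")
}

#' @export
print.hdx_isodist <- function(x, ...) {
  cat("<hdx_isodist>", length(x$mz), "peaks, z =", x$charge,
      sprintf("centroid m/z %.4f\n", sum(x$mz * x$intensity) /
                sum(x$intensity)))
  invisible(x)
}

#' Centroid (intensity-weighted mean mass) of an isotope distribution
#'
#' Computes the intensity-weighted mean m/z and, by default, converts it
#' to the neutral-mass scale: `mass = z * centroid(m/z) - z * m_proton`.
#' Set `charge_correct = FALSE` to obtain the raw m/z centroid (for
#' tables that are already on a processed mass scale).
#'
#' @param dist an [isotope_distribution()].
#' @param charge_correct convert to neutral mass (default `TRUE`).
#' @return centroid mass in Daltons (or Thomson if uncorrected).
#' @export
centroid <- function(dist, charge_correct = TRUE) {
  stopifnot(inherits(dist, "hdx_isodist"))
  c_mz <- sum(dist$mz * dist$intensity) / sum(dist$intensity)
  if (!charge_correct) return(c_mz)
  dist$charge * c_mz - dist$charge * .MASS_PROTON
}

.REQ_COLS <- c("peptide", "condition", "replicate", "time_s")

.validate_uptake_df <- function(df) {
  missing_cols <- setdiff(.REQ_COLS, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  has_cent <- "centroid_mz" %in% names(df) || "centroid_mass" %in% names(df)
  has_upt <- "uptake_da" %in% names(df)
  if (!has_cent && !has_upt)
    stop("need either a 'centroid_mz'/'centroid_mass' or an 'uptake_da' column")
  if (!is.numeric(df$time_s) || any(!is.finite(df$time_s)))
    stop("column 'time_s' must be numeric and finite (unparseable time?)")
  if (any(df$time_s < 0)) stop("negative exposure time")
  if (has_cent && "centroid_mz" %in% names(df) &&
      any(!is.finite(df$centroid_mz)))
    stop("non-finite centroid values")
  if ("sequence" %in% names(df) && all(c("start", "end") %in% names(df))) {
    span_ok <- is.na(df$start) | is.na(df$end) |
      nchar(df$sequence) == df$end - df$start + 1
    if (!all(span_ok))
      stop("sequence length does not match residue span for peptide(s): ",
           paste(unique(df$peptide[!span_ok]), collapse = ", "))
  }
  invisible(df)
}

#' Read an uptake table from CSV
#'
#' Canonical columns: `peptide, sequence, start, end, charge, condition,
#' replicate, time_s` plus either `centroid_mz` (raw centroid m/z; the
#' charge correction is applied downstream in [normalize_uptake()]) or
#' `uptake_da` (pre-computed deuterium uptake). A second dialect with
#' only `peptide, condition, replicate, time_s, uptake_da` is accepted.
#'
#' @param path CSV file path.
#' @param duplicates what to do with duplicated
#'   (peptide, condition, replicate, time) rows: `"error"` (default) or
#'   `"average"` the measurement columns.
#' @return a validated `hdx_data` data frame.
#' @export
read_uptake_csv <- function(path, duplicates = c("error", "average")) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_uptake_df(df)
  key <- interaction(df$peptide, df$condition, df$replicate, df$time_s,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    if (duplicates == "error")
      stop("duplicate (peptide, condition, replicate, time) rows; ",
           "pass duplicates = 'average' to average them")
    num <- intersect(c("centroid_mz", "centroid_mass", "uptake_da",
                       "uptake_frac"), names(df))
    agg <- stats::aggregate(df[num], by = list(key = key), FUN = mean)
    first <- df[!duplicated(key), setdiff(names(df), num), drop = FALSE]
    first <- first[order(key[!duplicated(key)]), , drop = FALSE]
    df <- cbind(first, agg[order(agg$key), num, drop = FALSE])
  }
  class(df) <- c("hdx_data", class(df))
  df
}

#' Write an uptake table to CSV
#'
#' @param data uptake table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_uptake_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Normalize centroids to deuterium uptake
#'
#' Converts centroid m/z values to the neutral-mass scale (optional) and
#' subtracts the time-zero reference so that `uptake(0) = 0`. The
#' reference is per (condition, replicate) when every replicate has a
#' `t = 0` record, otherwise the pooled mean of all `t = 0` centroids of
#' the peptide (recorded in the `reference` attribute). Tables that
#' already carry `uptake_da` (and no centroids) are returned unchanged,
#' making the operation idempotent.
#'
#' @param data uptake table with a centroid column.
#' @param reference `"auto"` (default: per-replicate when possible),
#'   `"replicate"` or `"pooled"`.
#' @param charge_correct apply the neutral-mass conversion
#'   `z * mz - z * m_proton` to `centroid_mz` (needs a `charge` column).
#' @return the table with an `uptake_da` column; `t = 0` reference rows
#'   have uptake exactly 0 under per-replicate referencing.
#' @export
normalize_uptake <- function(data, reference = c("auto", "replicate",
                                                 "pooled"),
                             charge_correct = TRUE) {
  reference <- match.arg(reference)
  .validate_uptake_df(data)
  has_cent <- "centroid_mz" %in% names(data) ||
    "centroid_mass" %in% names(data)
  if (!has_cent) {
    if (!"uptake_da" %in% names(data))
      stop("no centroid or uptake column to normalize")
    return(data)                      # already normalized: idempotent
  }
  if ("centroid_mass" %in% names(data)) {
    mass <- data$centroid_mass
  } else if (charge_correct) {
    if (!"charge" %in% names(data))
      stop("charge correction requires a 'charge' column")
    mass <- data$charge * data$centroid_mz -
      data$charge * .MASS_PROTON
  } else {
    mass <- data$centroid_mz
  }

  data$uptake_da <- NA_real_
  used_ref <- character(0)
  for (pep in unique(data$peptide)) {
    pi <- which(data$peptide == pep)
    sub <- data[pi, ]
    key <- paste(sub$condition, sub$replicate, sep = "/")
    t0 <- sub$time_s == 0
    per_rep_ok <- all(unique(key) %in% unique(key[t0]))
    mode <- if (reference == "auto") {
      if (per_rep_ok) "replicate" else "pooled"
    } else reference
    if (!any(t0))
      stop("no t = 0 reference for peptide '", pep, "'")
    if (mode == "replicate") {
      if (!per_rep_ok) {
        miss <- setdiff(unique(key), unique(key[t0]))
        stop("missing t = 0 reference for peptide '", pep,
             "', (condition, replicate) ", paste(miss, collapse = "; "))
      }
      ref <- tapply(mass[pi][t0], key[t0], mean)
      data$uptake_da[pi] <- mass[pi] - ref[key]
    } else {
      data$uptake_da[pi] <- mass[pi] - mean(mass[pi][t0])
    }
    used_ref[pep] <- mode
  }
  attr(data, "reference") <- used_ref
  if (!inherits(data, "hdx_data")) class(data) <- c("hdx_data", class(data))
  data
}

#' Normalize uptake by a fully deuterated control
#'
#' Divides uptake by the peptide's maximal (fully deuterated) uptake to
#' obtain fractional uptake. Values may slightly exceed 1 through noise;
#' values above 1.2 are flagged with a warning and in the `fd_flag`
#' column.
#'
#' @param data normalized uptake table (with `uptake_da`).
#' @param fd_control data frame with columns `peptide` and `fd_da`
#'   (positive maximal uptake in Daltons).
#' @return the table with `uptake_frac` and `fd_flag` columns.
#' @export
fd_normalize <- function(data, fd_control) {
  if (!"uptake_da" %in% names(data))
    stop("run normalize_uptake() first: no 'uptake_da' column")
  stopifnot(all(c("peptide", "fd_da") %in% names(fd_control)))
  fd <- fd_control$fd_da[match(data$peptide, fd_control$peptide)]
  if (any(is.na(fd)))
    stop("no fully deuterated control for peptide(s): ",
         paste(unique(data$peptide[is.na(fd)]), collapse = ", "))
  if (any(fd <= 0)) stop("fully deuterated control must be positive")
  data$uptake_frac <- data$uptake_da / fd
  data$fd_flag <- data$uptake_frac > 1.2
  if (any(data$fd_flag))
    warning(sum(data$fd_flag), " fractional uptake value(s) exceed 1.2",
            call. = FALSE)
  data
}

#' Extract one peptide's series from an uptake table
#'
#' @param data uptake table.
#' @param peptide peptide identifier.
#' @return the peptide's rows, with an `n_exchangeable` attribute when a
#'   sequence column is present.
#' @export
peptide_series <- function(data, peptide) {
  sub <- data[data$peptide == peptide, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown peptide: ", peptide)
  if ("sequence" %in% names(sub))
    attr(sub, "n_exchangeable") <- exchangeable_sites(sub$sequence[1])
  sub
}
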