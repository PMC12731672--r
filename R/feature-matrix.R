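#' Canonical fiducial feature registry
#'
#' The nine per-beat ECG fiducial features used everywhere in the package,
#' in their fixed canonical column order: heart rate (HR, beats/min), R-wave
#' height (R-H, mV), P-wave height (P-H, mV), PR interval (PRQ, ms), QT
#' interval (QT, ms), rate-corrected QT (QTC, ms), RR interval (RR-I, ms),
#' QRS duration (QRS, ms) and ST-segment level (ST, mV).
#'
#' @return Character vector of the 9 canonical feature names, in order.
#' @export
#' @examples
#' fiducial_features()
fiducial_features <- function() {
  c("HR", "R-H", "P-H", "PRQ", "QT", "QTC", "RR-I", "QRS", "ST")
}

#' Class labels of the three-way heart-condition problem
#'
#' Integer codes are fixed: arrhythmic = 0, healthy = 1, ischemic = 2.
#'
#' @return Character vector of class names ordered by integer code.
#' @export
class_labels <- function() {
  c("arrhythmic", "healthy", "ischemic")
}

# features whose invariants require strictly positive values
.positive_intervals <- c("PRQ", "QT", "QTC", "RR-I", "QRS")

#' Construct a feature matrix of labeled fiducial records
#'
#' The package's universal input container: an n x 9 numeric matrix in
#' canonical feature order plus an integer-coded class label per row and an
#' optional subject identifier per row.
#'
#' @param values Numeric matrix (or data frame) with 9 columns. If column
#'   names are present they are used to reorder into canonical order;
#'   unnamed input is assumed already canonical.
#' @param labels Class labels: integer codes in `0:2`, or character/factor
#'   values matched case-insensitively against [class_labels()].
#' @param subject_ids Optional character vector of per-row subject ids.
#' @param origin Optional character vector flagging `"original"` vs
#'   `"synthetic"` rows (set by [smote_oversample()]).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, subject_ids = NULL, origin = NULL) {
  feats <- fiducial_features()
  values <- as.matrix(values)
  if (ncol(values) != length(feats)) {
    stop("`values` must have exactly ", length(feats), " columns, got ",
         ncol(values), call. = FALSE)
  }
  if (!is.null(colnames(values))) {
    missing <- setdiff(feats, colnames(values))
    if (length(missing) > 0) {
      stop("missing required feature column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    values <- values[, feats, drop = FALSE]
  } else {
    colnames(values) <- feats
  }
  storage.mode(values) <- "double"
  labels <- normalize_labels(labels)
  if (length(labels) != nrow(values)) {
    stop("length(labels) [", length(labels), "] != number of rows [",
         nrow(values), "]", call. = FALSE)
  }
  if (!is.null(subject_ids)) {
    subject_ids <- as.character(subject_ids)
    stopifnot(length(subject_ids) == nrow(values))
  }
  if (!is.null(origin)) {
    origin <- as.character(origin)
    stopifnot(length(origin) == nrow(values))
  }
  structure(
    list(values = values, labels = labels, subject_ids = subject_ids,
         origin = origin),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", n_records(x), " records x ",
      ncol(x$values), " fiducial features\n", sep = "")
  cts <- class_counts(x)
  cat("  classes: ", paste(names(cts), cts, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$subject_ids)) {
    cat("  subjects: ", length(unique(x$subject_ids)), "\n", sep = "")
  }
  invisible(x)
}

#' Number of records in a feature matrix
#' @param x A `feature_matrix`.
#' @return Integer row count.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  nrow(x$values)
}

#' Per-class record counts
#' @param x A `feature_matrix`.
#' @return Named integer vector over the three classes (in code order);
#'   always sums to [n_records()].
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  cts <- tabulate(x$labels + 1L, nbins = 3L)
  names(cts) <- class_labels()
  cts
}

#' @export
`[.feature_matrix` <- function(x, i, ...) {
  feature_matrix(
    x$values[i, , drop = FALSE],
    x$labels[i],
    subject_ids = if (!is.null(x$subject_ids)) x$subject_ids[i],
    origin = if (!is.null(x$origin)) x$origin[i]
  )
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  df <- as.data.frame(x$values, check.names = FALSE)
  df <- cbind(
    subject_id = if (is.null(x$subject_ids)) NA_character_ else x$subject_ids,
    label = class_labels()[x$labels + 1L],
    df,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

# Map labels (codes, character, or factor) to integer codes 0:2.
normalize_labels <- function(labels) {
  if (is.numeric(labels)) {
    codes <- as.integer(labels)
    bad <- which(is.na(codes) | codes < 0L | codes > 2L |
                   (is.double(labels) & labels != codes))
    if (length(bad) > 0) {
      stop("invalid class code(s) at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           "; codes must be integers in 0:2", call. = FALSE)
    }
    return(codes)
  }
  lab <- tolower(trimws(as.character(labels)))
  codes <- match(lab, class_labels()) - 1L
  bad <- which(is.na(codes))
  if (length(bad) > 0) {
    stop("unknown class label(s): ",
         paste(unique(as.character(labels)[bad]), collapse = ", "),
         " (expected one of: ", paste(class_labels(), collapse = ", "),
         ", case-insensitive)", call. = FALSE)
  }
  codes
}

#' Read a fiducial feature CSV
#'
#' Reads the canonical CSV schema
#' `subject_id,label,HR,R-H,P-H,PRQ,QT,QTC,RR-I,QRS,ST` (the `subject_id`
#' column is optional, and file column order is irrelevant: columns are
#' re-ordered to the canonical registry). Labels are matched
#' case-insensitively. Unknown columns are dropped with a warning.
#'
#' @param path Path to a CSV file with a header row.
#' @return A [feature_matrix()].
#' @export
read_fiducial_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  feats <- fiducial_features()
  required <- c("label", feats)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(df), c("subject_id", required))
  if (length(unknown) > 0) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow(df), length(feats),
                 dimnames = list(NULL, feats))
  for (f in feats) {
    raw <- trimws(df[[f]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(tolower(raw) %in% c("na", "nan", "")))
    if (length(bad) > 0) {
      stop("unparseable numeric value ", sQuote(raw[bad[1]]),
           " in column ", sQuote(f), " at data row ", bad[1], call. = FALSE)
    }
    num[tolower(raw) == "nan"] <- NaN
    vals[, f] <- num
  }
  sid <- NULL
  if ("subject_id" %in% names(df)) {
    sid <- as.character(df[["subject_id"]])
    if (all(is.na(sid) | sid == "")) sid <- NULL
  }
  feature_matrix(vals, df[["label"]], subject_ids = sid)
}

#' Write a fiducial feature CSV
#'
#' Writes the canonical header
#' `subject_id,label,HR,R-H,P-H,PRQ,QT,QTC,RR-I,QRS,ST`. Numeric values are
#' emitted with 17 significant digits so the CSV round-trip is value-exact
#' for finite doubles.
#'
#' @param data A [feature_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fiducial_csv <- function(data, path) {
  stopifnot(inherits(data, "feature_matrix"))
  feats <- fiducial_features()
  header <- c("subject_id", "label", feats)
  n <- n_records(data)
  sid <- if (is.null(data$subject_ids)) rep("", n) else data$subject_ids
  num <- apply(data$values, 2, function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col) & !is.nan(col)] <- "NA"
    out
  })
  if (n == 0) num <- matrix(character(0), 0, length(feats))
  body <- cbind(sid, class_labels()[data$labels + 1L], num)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  if (n > 0) {
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Filter invalid fiducial records
#'
#' Row-level analogue of beat filtering: rows violating the record
#' invariants (all nine features finite; heart rate positive; PR, QT, QTc,
#' RR and QRS intervals positive) are excluded and counted by the first
#' rule they violate. Validation never throws on bad rows.
#'
#' @param data A [feature_matrix()].
#' @return List with `clean` (a `feature_matrix` of the surviving rows) and
#'   `report` (named integer vector of rejection counts by reason:
#'   `non_finite`, `non_positive_rate`, `non_positive_interval`). Always
#'   `n_records(clean) + sum(report) == n_records(data)`.
#' @export
validate_records <- function(data) {
  stopifnot(inherits(data, "feature_matrix"))
  v <- data$values
  non_finite <- apply(v, 1, function(r) any(!is.finite(r)))
  bad_rate <- !non_finite & v[, "HR"] <= 0
  bad_interval <- !non_finite & !bad_rate &
    apply(v[, .positive_intervals, drop = FALSE] <= 0, 1, any)
  if (nrow(v) == 0) non_finite <- bad_rate <- bad_interval <- logical(0)
  keep <- !(non_finite | bad_rate | bad_interval)
  report <- c(
    non_finite = sum(non_finite),
    non_positive_rate = sum(bad_rate),
    non_positive_interval = sum(bad_interval)
  )
  list(clean = data[keep], report = report)
}

#' Fit and apply per-feature z-score standardization
#'
#' Fits per-feature location (mean) and scale (standard deviation) on
#' `train` and applies `(x - mean) / sd` column-wise to `apply_to`.
#' Constant columns get scale 1 with a warning, so they standardize to all
#' zeros. The returned scaler is a plain list and can be re-applied with
#' [apply_scaler()].
#'
#' @param train A `feature_matrix` with at least 2 rows; statistics are
#'   fitted here.
#' @param apply_to A `feature_matrix` to transform (defaults to `train`).
#' @return List with `scaled` (transformed `apply_to`) and `scaler`
#'   (class `fiducial_scaler`: named `center` and `scale` vectors).
#' @export
standardize_features <- function(train, apply_to = train) {
  stopifnot(inherits(train, "feature_matrix"))
  if (n_records(train) < 2) {
    stop("need at least 2 training records to fit a scaler", call. = FALSE)
  }
  center <- colMeans(train$values)
  scale <- apply(train$values, 2, stats::sd)
  const <- !is.finite(scale) | scale <= 0
  if (any(const)) {
    warning("constant column(s) ", paste(names(scale)[const], collapse = ", "),
            ": using scale 1", call. = FALSE)
    scale[const] <- 1
  }
  scaler <- structure(list(center = center, scale = scale),
                      class = "fiducial_scaler")
  list(scaled = apply_scaler(scaler, apply_to), scaler = scaler)
}

#' Apply a fitted scaler to a feature matrix
#' @param scaler A `fiducial_scaler` from [standardize_features()].
#' @param data A `feature_matrix`.
#' @return The standardized `feature_matrix`.
#' @export
apply_scaler <- function(scaler, data) {
  stopifnot(inherits(scaler, "fiducial_scaler"),
            inherits(data, "feature_matrix"))
  vals <- sweep(sweep(data$values, 2, scaler$center, "-"),
                2, scaler$scale, "/")
  feature_matrix(vals, data$labels, subject_ids = data$subject_ids,
                 origin = data$origin)
}
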