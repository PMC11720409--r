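#' Construct an expression matrix
#'
#' The central container of the package: a reagents-by-samples numeric
#' matrix carrying an explicit scale tag so that downstream stages can
#' refuse inputs on the wrong scale (e.g. double z-scaling, or CVs on
#' harmonized data).
#'
#' @param values Numeric matrix, reagents in rows (row names = reagent
#'   ids), samples in columns (column names = sample ids).
#' @param scale One of `"LINEAR_RFU"` (raw aptamer fluorescence,
#'   strictly positive), `"NPX_LOG2"` (antibody-panel NPX, already
#'   log2), `"LOG2"`, or `"ZSCORED"`.
#' @param platform One of `"SOMA_A"`, `"SOMA_B"`, `"OLINK"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `scale`, `platform`.
#' @export
expression_matrix <- function(values, scale, platform) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  scale <- match.arg(scale, .scales)
  platform <- match.arg(platform, .platforms)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have reagent row names and sample column names")
  }
  if (anyNA(rownames(values)) || any(rownames(values) == "")) {
    stop("missing reagent ids in row names")
  }
  if (anyNA(colnames(values)) || any(colnames(values) == "")) {
    stop("missing sample ids in column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate reagent ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (scale == "LINEAR_RFU" && any(values <= 0, na.rm = TRUE)) {
    stop("LINEAR_RFU values must be strictly positive")
  }
  structure(list(values = values, scale = scale, platform = platform),
            class = "expression_matrix")
}

#' @export
#' @method print expression_matrix
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d reagents x %d samples | scale %s | platform %s\n",
              nrow(x$values), ncol(x$values), x$scale, x$platform))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Reagent and sample identifiers of an expression matrix
#' @param m An `expression_matrix`.
#' @return Character vector of ids in matrix order.
#' @export
reagent_ids <- function(m) rownames(m$values)

#' @rdname reagent_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Read an abundance table in one of the two platform dialects
#'
#' `ADAT_WIDE` is a plain wide delimited table: first column the reagent
#' id, one further column per sample, values on the raw linear RFU
#' scale.  `NPX_LONG` is one row per measurement with columns
#' `sample_id`, `reagent_id`, `npx` (plus optional extras such as
#' `panel`), values on the log2 NPX scale.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"ADAT_WIDE"` or `"NPX_LONG"`.
#' @param platform Platform tag for the resulting matrix.
#' @param sep Field separator (default tab).
#' @return An [expression_matrix()] with scale `LINEAR_RFU`
#'   (`ADAT_WIDE`) or `NPX_LOG2` (`NPX_LONG`).
#' @export
read_expression <- function(path, dialect = c("ADAT_WIDE", "NPX_LONG"),
                            platform, sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (dialect == "ADAT_WIDE") {
    if (ncol(df) < 2L) stop("malformed header in ", path,
                            ": need a reagent id column plus sample columns")
    ids <- as.character(df[[1L]])
    num <- df[-1L]
    for (j in seq_along(num)) {
      v <- num[[j]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
        stop(sprintf("non-numeric cell in column '%s', row %d of %s",
                     names(num)[j], if (length(bad)) bad[1L] else NA_integer_,
                     path))
      }
    }
    values <- as.matrix(num)
    rownames(values) <- ids
    expression_matrix(values, "LINEAR_RFU", platform)
  } else {
    need <- c("sample_id", "reagent_id", "npx")
    if (!all(need %in% names(df))) {
      stop("malformed header in ", path, ": NPX_LONG needs columns ",
           paste(need, collapse = ", "))
    }
    if (!is.numeric(df$npx)) {
      bad <- which(is.na(suppressWarnings(as.numeric(df$npx))) & !is.na(df$npx))
      stop(sprintf("non-numeric cell in column 'npx', row %d of %s",
                   if (length(bad)) bad[1L] else NA_integer_, path))
    }
    key <- paste(df$sample_id, df$reagent_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE][1L, ]
      stop(sprintf("duplicate (sample, reagent) row in %s: (%s, %s)",
                   path, d$sample_id, d$reagent_id))
    }
    rs <- unique(as.character(df$reagent_id))
    ss <- unique(as.character(df$sample_id))
    values <- matrix(NA_real_, nrow = length(rs), ncol = length(ss),
                     dimnames = list(rs, ss))
    values[cbind(match(df$reagent_id, rs), match(df$sample_id, ss))] <-
      as.numeric(df$npx)
    expression_matrix(values, "NPX_LOG2", platform)
  }
}

#' Write an expression matrix in a platform dialect
#'
#' Inverse of [read_expression()]; the written file round-trips.
#'
#' @inheritParams read_expression
#' @param m An `expression_matrix`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, dialect = c("ADAT_WIDE", "NPX_LONG"),
                             sep = "\t") {
  dialect <- match.arg(dialect)
  if (dialect == "ADAT_WIDE") {
    df <- data.frame(reagent_id = rownames(m$values),
                     m$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  } else {
    long <- expand.grid(reagent_id = rownames(m$values),
                        sample_id = colnames(m$values),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    long$npx <- as.vector(m$values)
    long <- long[, c("sample_id", "reagent_id", "npx")]
    utils::write.table(long, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Harmonize an expression matrix to per-reagent z-scores
#'
#' Raw linear RFU values are first log2-transformed; log2-scale inputs
#' (including NPX) are taken as-is.  Every non-constant reagent row is
#' then centered to mean 0 and scaled to SD 1 (n-1 denominator).
#' Constant rows carry no usable signal on the z scale and are dropped
#' with a warning; the dropped ids are recorded in the
#' `"excluded_reagents"` attribute of the result.
#'
#' @param m An `expression_matrix` on scale `LINEAR_RFU`, `NPX_LOG2`,
#'   or `LOG2`.
#' @return An `expression_matrix` with scale `ZSCORED`.
#' @export
log2_zscale <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale == "ZSCORED") {
    stop("input is already z-scored; refusing to double-scale")
  }
  v <- m$values
  if (m$scale == "LINEAR_RFU") {
    if (any(v <= 0, na.rm = TRUE)) {
      stop("non-positive value under LINEAR_RFU; cannot log2-transform")
    }
    v <- log2(v)
  }
  sds <- apply(v, 1L, stats::sd, na.rm = TRUE)
  constant <- !is.na(sds) & sds == 0
  if (any(constant)) {
    warning(sprintf("excluding %d constant reagent row(s): z-score undefined",
                    sum(constant)))
  }
  keep <- !constant
  v <- v[keep, , drop = FALSE]
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1L, stats::sd, na.rm = TRUE)
  z <- (v - mu) / sdv
  out <- expression_matrix(z, "ZSCORED", m$platform)
  attr(out, "excluded_reagents") <- rownames(m$values)[constant]
  out
}

#' Restrict two expression matrices to their shared samples
#'
#' Correlation between platforms is computed on overlapping
#' individuals only; this returns both matrices restricted to the
#' sample intersection, in identical column order (order of first
#' appearance in `a`).
#'
#' @param a,b `expression_matrix` objects.
#' @return List with elements `a`, `b` (restricted matrices) and
#'   `n_overlap`.
#' @export
align_overlap <- function(a, b) {
  stopifnot(inherits(a, "expression_matrix"), inherits(b, "expression_matrix"))
  common <- intersect(sample_ids(a), sample_ids(b))
  if (length(common) == 0L) {
    stop("no overlapping samples between the two matrices")
  }
  sub <- function(m) {
    expression_matrix(m$values[, common, drop = FALSE], m$scale, m$platform)
  }
  list(a = sub(a), b = sub(b), n_overlap = length(common))
}
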