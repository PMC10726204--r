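#' @section Vegetation-index library:
#' The package carries a fixed library of 35 yield-sensitive multispectral
#' vegetation indices defined over five plot-mean band reflectances: blue (B),
#' green (G), red (R), red edge (RE) and near infrared (NIR). Two formula
#' dialects are available. The default `"as_printed"` dialect evaluates every
#' formula exactly as tabulated in the source index compilation, including a
#' handful of forms that deviate from the wider literature (a TVI without the
#' square root, a chained-division CCCI, non-standard ATSAVI/IVI/NLI/WDRVI
#' coefficients). The `"corrected"` dialect substitutes the standard
#' literature form only where the tabulated form is a known typographic
#' variant: TVI becomes sqrt(NDVI + 0.5) and CCCI becomes NDRE/NDVI. All
#' other formulas — including the chlorophyll-absorption indices TCARI and
#' MCARI, whose tabulated forms already match their standard definitions —
#' are identical in both dialects.
#' @name vegindex
NULL

# Registry of index definitions, in canonical table order. Each entry is a
# function of an environment-like list with elements blue, green, red,
# red_edge, nir (vectors). Zero denominators yield NA via safe_div().
# `corrected` is NULL when the dialects agree.
.vi_registry <- local({
  nd <- function(a, b) safe_div(a - b, a + b)
  list(
    NDVI  = list(printed = function(b) nd(b$nir, b$red)),
    NDRE  = list(printed = function(b) nd(b$nir, b$red_edge)),
    GNDVI = list(printed = function(b) nd(b$nir, b$green)),
    # As printed the formula is the chained division
    # (NIR-RE)/(NIR+RE)/(NIR-R)/(NIR+R), which left-associates to
    # (NIR-RE) / [(NIR+RE)(NIR-R)(NIR+R)]; the corrected form is NDRE/NDVI.
    CCCI  = list(
      printed = function(b) safe_div(b$nir - b$red_edge,
                                     (b$nir + b$red_edge) * (b$nir - b$red) * (b$nir + b$red)),
      corrected = function(b) safe_div(nd(b$nir, b$red_edge), nd(b$nir, b$red))
    ),
    GRVI  = list(printed = function(b) safe_div(b$nir, b$green)),
    RGR   = list(printed = function(b) safe_div(b$red, b$green)),
    RRI1  = list(printed = function(b) safe_div(b$nir, b$red_edge)),
    RRI2  = list(printed = function(b) safe_div(b$red_edge, b$red)),
    # Coefficients exactly as tabulated (note the bare "1.222" constant).
    ATSAVI = list(printed = function(b)
      safe_div(1.22 * (b$nir - 1.22 * b$red - 1.22),
               1.22 * b$nir + b$red - 1.22 * 0.03 + 0.08 * (1 + 1.222))),
    CIg   = list(printed = function(b) safe_div(b$nir, b$green) - 1),
    CIre  = list(printed = function(b) safe_div(b$nir, b$red_edge) - 1),
    IVI   = list(printed = function(b) safe_div(b$nir - 0.03, 1.22 * b$red)),
    DVI   = list(printed = function(b) b$nir - b$red),
    WDVI  = list(printed = function(b) b$nir - 1.22 * b$red),
    TVI   = list(
      printed = function(b) nd(b$nir, b$red) + 0.5,
      corrected = function(b) {
        v <- nd(b$nir, b$red) + 0.5
        v[!is.na(v) & v < 0] <- NA_real_
        sqrt(v)
      }
    ),
    WDRVI = list(printed = function(b) safe_div(0.1 * b$nir - b$red, 0.1 * b$nir + b$red)),
    TNDVI = list(printed = function(b) safe_div(b$nir - b$red, b$nir + b$red + 0.5)),
    SAVI  = list(printed = function(b) 1.5 * safe_div(b$nir - b$red, b$nir + b$red + 0.16)),
    GDVI  = list(printed = function(b) b$nir - b$green),
    GSAVI = list(printed = function(b) 1.5 * safe_div(b$nir - b$green, b$nir + b$green + 0.5)),
    NormG   = list(printed = function(b) safe_div(b$green, b$nir + b$red + b$green)),
    NormNIR = list(printed = function(b) safe_div(b$nir, b$red + b$green + b$nir)),
    NormR   = list(printed = function(b) safe_div(b$red, b$red + b$green + b$nir)),
    NGRDI = list(printed = function(b) nd(b$green, b$red)),
    RI    = list(printed = function(b) nd(b$red, b$green)),
    CVI   = list(printed = function(b) b$nir * safe_div(b$red, b$green^2)),
    RVI   = list(printed = function(b) safe_div(b$nir, b$red)),
    NLI   = list(printed = function(b) safe_div(0.12 * b$nir - b$red, 0.12 * b$nir + b$red)),
    MNLI  = list(printed = function(b)
      safe_div(1.5 * b$nir^2 - 1.5 * b$green, b$nir^2 + b$red + 0.5)),
    OSAVI = list(printed = function(b) safe_div(b$nir - b$red, b$nir + b$red + 0.16)),
    TCARI = list(printed = function(b)
      3 * ((b$red_edge - b$red) - 0.2 * (b$red_edge - b$green) * safe_div(b$red_edge, b$red))),
    MCARI = list(printed = function(b)
      ((b$red_edge - b$red) - 0.2 * (b$red_edge - b$green)) * safe_div(b$red_edge, b$red)),
    GCI   = list(printed = function(b) safe_div(b$nir, b$green) - 1),
    RECI  = list(printed = function(b) safe_div(b$nir, b$red_edge) - 1),
    MRVI  = list(printed = function(b)
      safe_div(safe_div(b$nir, b$red) - 1, safe_div(b$nir, b$red) + 1))
  )
})

.band_names <- c("blue", "green", "red", "red_edge", "nir")

#' Names of the 35 vegetation indices
#'
#' Returns the names of the vegetation-index library in canonical table
#' order (NDVI first, MRVI last). This order is also the tie-break order
#' used throughout the selection module.
#'
#' @return Character vector of length 35.
#' @export
#' @examples
#' vi_names()
vi_names <- function() names(.vi_registry)

# Resolve a dialect argument.
match_dialect <- function(dialect) match.arg(dialect, c("as_printed", "corrected"))

# Normalize band input: accept a list/data.frame plus ... overrides; absent
# bands become NA so indices that do not reference them still compute.
as_bands <- function(bands = NULL, ...) {
  dots <- list(...)
  if (is.null(bands)) bands <- list()
  bands <- as.list(bands)[intersect(names(bands), .band_names)]
  bands[names(dots)] <- dots
  unknown <- setdiff(names(bands), .band_names)
  if (length(unknown)) {
    vi_stop(sprintf("unknown band name(s): %s", paste(unknown, collapse = ", ")),
            "viselect_schema_error")
  }
  n <- max(c(1L, lengths(bands)))
  out <- lapply(.band_names, function(nm) {
    v <- bands[[nm]]
    if (is.null(v)) return(rep(NA_real_, n))
    stopifnot_numeric(v, sprintf("band '%s'", nm))
    if (length(v) == 1L) rep(as.numeric(v), n) else as.numeric(v)
  })
  names(out) <- .band_names
  if (length(unique(c(1L, lengths(bands)))) > 2L) {
    vi_stop("band vectors must share a common length (or be scalars)",
            "viselect_schema_error")
  }
  out
}

#' Validate band reflectances
#'
#' Checks that supplied band reflectances are finite and warns (without
#' failing) when values fall outside the physical \[0, 1\] reflectance range,
#' which radiometric pipelines occasionally overshoot.
#'
#' @param bands A list or data.frame with (a subset of) columns `blue`,
#'   `green`, `red`, `red_edge`, `nir`.
#' @param ... Individual bands given as named vectors, overriding `bands`.
#' @return Invisibly, a named integer vector counting out-of-range values
#'   per band.
#' @export
validate_bands <- function(bands = NULL, ...) {
  b <- as_bands(bands, ...)
  counts <- vapply(.band_names, function(nm) {
    v <- b[[nm]]
    if (all(is.na(v))) return(0L)
    if (any(!is.finite(v[!is.na(v)]))) {
      vi_stop(sprintf("band '%s' contains non-finite values", nm),
              "viselect_schema_error")
    }
    sum(v < 0 | v > 1, na.rm = TRUE)
  }, integer(1))
  if (any(counts > 0)) {
    bad <- counts[counts > 0]
    warning(sprintf("reflectance outside [0, 1]: %s",
                    paste(sprintf("%s (%d)", names(bad), bad), collapse = ", ")),
            call. = FALSE)
  }
  invisible(counts)
}

#' Compute one vegetation index
#'
#' Evaluates a single index formula at the given band reflectances. Values
#' whose denominator is exactly zero are returned as `NA` (missing), never
#' clamped or substituted.
#'
#' @param name Index name; must be one of [vi_names()] (case sensitive).
#' @param bands,... Band reflectances, see [validate_bands()].
#' @param dialect `"as_printed"` (default) or `"corrected"`; see
#'   the package overview for what the corrected dialect changes.
#' @return Numeric vector of index values.
#' @export
#' @examples
#' compute_index("NDVI", nir = 0.5, red = 0.1)
compute_index <- function(name, bands = NULL, ..., dialect = "as_printed") {
  dialect <- match_dialect(dialect)
  if (length(name) != 1L || !name %in% vi_names()) {
    vi_stop(sprintf("unknown index name: '%s'", paste(name, collapse = ",")),
            "viselect_name_error")
  }
  entry <- .vi_registry[[name]]
  f <- if (dialect == "corrected" && !is.null(entry$corrected)) entry$corrected else entry$printed
  f(as_bands(bands, ...))
}

#' Compute the full vegetation-index table
#'
#' Evaluates all 35 indices for every plot of a plot-level band table,
#' producing one row per plot. Rows where any index is missing (zero
#' denominator) are flagged, and a per-index missing-value report is
#' attached.
#'
#' @param plot_table A data.frame with a `plot_id` column (optional; row
#'   numbers are used if absent) and the five band columns `blue`, `green`,
#'   `red`, `red_edge`, `nir`.
#' @param dialect Formula dialect, see [compute_index()].
#' @return A data.frame of class `vi_table` with `plot_id` plus 35 index
#'   columns, and attributes `dialect`, `incomplete` (logical per row) and
#'   `missing_report` (NA count per index).
#' @export
compute_all <- function(plot_table, dialect = "as_printed") {
  dialect <- match_dialect(dialect)
  missing_cols <- setdiff(.band_names, names(plot_table))
  if (length(missing_cols)) {
    vi_stop(sprintf("plot table is missing band column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "viselect_schema_error")
  }
  b <- as_bands(plot_table[.band_names])
  vals <- lapply(vi_names(), function(nm) {
    entry <- .vi_registry[[nm]]
    f <- if (dialect == "corrected" && !is.null(entry$corrected)) entry$corrected else entry$printed
    f(b)
  })
  names(vals) <- vi_names()
  out <- data.frame(
    plot_id = if ("plot_id" %in% names(plot_table)) plot_table$plot_id else seq_len(nrow(plot_table)),
    vals, check.names = FALSE, stringsAsFactors = FALSE
  )
  m <- as.matrix(out[vi_names()])
  structure(out,
            dialect = dialect,
            incomplete = rowSums(is.na(m)) > 0,
            missing_report = colSums(is.na(m)),
            class = c("vi_table", "data.frame"))
}

#' @export
print.vi_table <- function(x, ...) {
  cat(sprintf("<vi_table> %d plots x %d indices (dialect: %s)\n",
              nrow(x), length(vi_names()), attr(x, "dialect")))
  inc <- attr(x, "incomplete")
  if (any(inc)) cat(sprintf("  %d row(s) contain missing index values\n", sum(inc)))
  print.data.frame(utils::head(as.data.frame(x)[, seq_len(min(6, ncol(x)))], 4))
  invisible(x)
}

# Feature matrix (plots x 35) from a vi_table or plain data.frame.
vi_feature_matrix <- function(vitable) {
  cols <- intersect(vi_names(), names(vitable))
  if (!length(cols)) vi_stop("no vegetation-index columns found", "viselect_schema_error")
  as.matrix(as.data.frame(vitable)[cols])
}

#' Write a vegetation-index table with sidecar metadata
#'
#' Writes the index table as CSV and records the formula dialect, package
#' version and column names in a sidecar JSON file (`<path>.json`).
#'
#' @param vitable A `vi_table` from [compute_all()].
#' @param path Output CSV path.
#' @return Invisibly, the CSV path.
#' @export
write_vi_table <- function(vitable, path) {
  utils::write.csv(as.data.frame(vitable), path, row.names = FALSE)
  meta <- list(
    dialect = attr(vitable, "dialect") %||% "as_printed",
    package = "viselect",
    version = as.character(utils::packageVersion("viselect")),
    indices = vi_names(),
    n_missing = as.list(attr(vitable, "missing_report") %||% integer())
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
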