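#' Read a spectrum table from CSV
#'
#' Two layouts are supported. `wide`: one row per sample; non-numeric
#' column headers are metadata (must include `sample_id`), numeric headers
#' are wavenumbers. `long`: columns exactly
#' `(sample_id, wavenumber, absorbance)`, with per-sample metadata in an
#' optional sidecar CSV (`meta_path`) keyed by `sample_id`. Samples keep
#' the order in which they are first encountered.
#'
#' @param path CSV path (UTF-8, "." decimal, comma delimiter).
#' @param layout "wide" or "long".
#' @param meta_path optional metadata sidecar CSV for the long layout
#'   (columns `sample_id, genotype, group, trait_ar10_ibap,
#'   trait_ar21_ibap, trait_ar21_ibam`).
#' @return a [spectrum_table].
#' @export
read_spectra_csv <- function(path, layout = c("wide", "long"),
                             meta_path = NULL) {
  layout <- match.arg(layout)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1) {
    stop("ragged CSV: rows have differing field counts in ", path,
         call. = FALSE)
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    hdr <- names(df)
    wn <- suppressWarnings(as.numeric(hdr))
    meta_cols <- which(is.na(wn))
    chan_cols <- which(!is.na(wn))
    if (length(chan_cols) < 2) {
      stop("wide CSV: fewer than 2 parseable wavenumber headers in ", path,
           call. = FALSE)
    }
    if (!"sample_id" %in% hdr[meta_cols]) {
      stop("wide CSV: no sample_id metadata column in ", path,
           call. = FALSE)
    }
    ab <- as.matrix(df[, chan_cols, drop = FALSE])
    if (!is.numeric(ab)) {
      stop("wide CSV: non-numeric absorbance values in ", path,
           call. = FALSE)
    }
    spectrum_table(ab, wn[chan_cols],
                   meta = df[, meta_cols, drop = FALSE])
  } else {
    need <- c("sample_id", "wavenumber", "absorbance")
    if (!identical(sort(names(df)), sort(need))) {
      stop("long CSV must have columns exactly (sample_id, wavenumber, ",
           "absorbance); got: ", paste(names(df), collapse = ", "),
           call. = FALSE)
    }
    df$sample_id <- as.character(df$sample_id)
    key <- paste(df$sample_id, df$wavenumber)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop("long CSV: duplicated (sample, wavenumber) pair: ", d,
           call. = FALSE)
    }
    ids <- unique(df$sample_id)
    wns <- unique(df$wavenumber)
    if (nrow(df) != length(ids) * length(wns)) {
      stop("long CSV: samples do not share a common wavenumber set",
           call. = FALSE)
    }
    ab <- matrix(NA_real_, length(ids), length(wns),
                 dimnames = list(ids, wns))
    ab[cbind(match(df$sample_id, ids), match(df$wavenumber, wns))] <-
      df$absorbance
    meta <- tibble(sample_id = ids)
    if (!is.null(meta_path)) {
      ms <- read.csv(meta_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
      ms$sample_id <- as.character(ms$sample_id)
      meta <- left_join(meta, as_tibble(ms), by = "sample_id")
    }
    spectrum_table(ab, wns, meta = meta)
  }
}

#' Write a spectrum table to CSV
#'
#' @param table a [spectrum_table].
#' @param path output CSV path.
#' @param layout "wide" (metadata columns then wavenumber columns) or
#'   "long" (`sample_id, wavenumber, absorbance` plus a metadata sidecar).
#' @param meta_path sidecar path for the long layout; defaults to
#'   `<path minus .csv>_meta.csv`.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(table, path, layout = c("wide", "long"),
                              meta_path = NULL) {
  stopifnot(inherits(table, "spectrum_table"))
  layout <- match.arg(layout)
  if (layout == "wide") {
    ab <- apply(table$absorbance, c(1, 2), num17)
    colnames(ab) <- num17(table$axis)
    out <- data.frame(df_num17(as.data.frame(table$meta)),
                      as.data.frame(ab), check.names = FALSE)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    long <- data.frame(
      sample_id = rep(table$meta$sample_id, each = length(table$axis)),
      wavenumber = num17(rep(table$axis, nrow(table$absorbance))),
      absorbance = num17(as.vector(t(table$absorbance))))
    write.csv(long, path, row.names = FALSE, quote = FALSE)
    if (is.null(meta_path)) {
      meta_path <- paste0(sub("\\.csv$", "", path), "_meta.csv")
    }
    write.csv(df_num17(as.data.frame(table$meta)), meta_path,
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# full-precision decimal rendering so float64 CSV round-trips are exact
num17 <- function(x) sprintf("%.17g", x)

df_num17 <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      v <- num17(df[[j]])
      v[is.na(df[[j]])] <- NA
      df[[j]] <- v
    }
  }
  df
}
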