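#' Reference component spectral library
#'
#' Named reference spectra (hemicellulose monomer signatures, lignin
#' variants, pectin, proteins, paraffin, ...) on a shared wavenumber axis.
#' Spectra must be nonnegative; they are unit-L2-normalized on construction
#' so EMSC coefficients are comparable across components.
#'
#' @param spectra numeric matrix, n_components x n_channels.
#' @param axis wavenumber axis (cm^-1).
#' @param names unique component names.
#' @param categories component categories; one of "hemicellulose_monomer",
#'   "cellulose", "lignin", "pectin", "protein", "lipid", "paraffin",
#'   "other". Recycled if length 1.
#' @return object of class `component_library`.
#' @export
component_library <- function(spectra, axis, names,
                              categories = "other") {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  ca <- canonical_axis(axis)
  if (ncol(spectra) != length(ca$axis)) {
    stop("library spectra have ", ncol(spectra),
         " channels but the axis has ", length(ca$axis), call. = FALSE)
  }
  spectra <- spectra[, ca$order, drop = FALSE]
  if (any(spectra < 0)) {
    stop("component spectra must be nonnegative", call. = FALSE)
  }
  if (length(names) != nrow(spectra) || anyDuplicated(names)) {
    stop("component names must be unique and match the spectra rows",
         call. = FALSE)
  }
  allowed <- c("hemicellulose_monomer", "cellulose", "lignin", "pectin",
               "protein", "lipid", "paraffin", "other")
  categories <- rep_len(as.character(categories), nrow(spectra))
  if (!all(categories %in% allowed)) {
    stop("invalid component category; allowed: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  nrm <- sqrt(rowSums(spectra^2))
  if (any(nrm == 0)) stop("zero-norm component spectrum", call. = FALSE)
  spectra <- spectra / nrm
  rownames(spectra) <- names
  structure(
    list(axis = ca$axis, spectra = spectra,
         info = tibble(name = as.character(names), category = categories)),
    class = "component_library"
  )
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library> %d components x %d channels\n",
              nrow(x$spectra), length(x$axis)))
  print(x$info, n = Inf)
  invisible(x)
}

#' @export
dim.component_library <- function(x) dim(x$spectra)

#' Read / write a component library as wide CSV
#'
#' Layout: columns `name`, `category`, then numeric wavenumber headers.
#'
#' @param path CSV path.
#' @return [read_component_library()] returns a [component_library];
#'   `write_component_library()` returns `path` invisibly.
#' @export
read_component_library <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(df)
  wn <- suppressWarnings(as.numeric(hdr))
  chan <- which(!is.na(wn))
  if (!all(c("name", "category") %in% hdr)) {
    stop("library CSV needs 'name' and 'category' columns", call. = FALSE)
  }
  component_library(as.matrix(df[, chan, drop = FALSE]), wn[chan],
                    names = df$name, categories = df$category)
}

#' @rdname read_component_library
#' @param library a [component_library].
#' @export
write_component_library <- function(library, path) {
  stopifnot(inherits(library, "component_library"))
  sp <- apply(library$spectra, c(1, 2), num17)
  colnames(sp) <- num17(library$axis)
  out <- cbind(name = library$info$name, category = library$info$category,
               as.data.frame(sp), stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
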