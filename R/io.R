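# CSV readers/writers for the package's three canonical table schemas, and
# a minimal JCAMP-DX reader. CSV is the canonical on-disk format: header
# names are exact, UTF-8, "." decimal. Header comment lines start with "#"
# and may carry key: value metadata (protein_conc_M, tau_s, wavelength_nm).

read_csv_with_comments <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.+?)\\s*$", cl))[[1L]]
    if (length(m) == 3L) {
      val <- suppressWarnings(as.numeric(m[3L]))
      meta[[m[2L]]] <- if (is.na(val)) m[3L] else val
    }
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2L)
    stop("no data rows found in ", path, call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(df = df, meta = meta)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing mandatory column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
}

check_numeric_column <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v)) {
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) & !is.na(v))
    if (length(bad))
      stop(sprintf("parse error in %s: non-numeric value '%s' in column %s, row %d",
                   path, v[bad[1L]], col, bad[1L]), call. = FALSE)
    vn
  } else if (anyNA(v)) {
    stop(sprintf("parse error in %s: missing value in column %s, row %d",
                 path, col, which(is.na(v))[1L]), call. = FALSE)
  } else as.numeric(v)
}

#' Read a delimited table as a typed spectroscopy object
#'
#' Dispatches on `schema` to one of the package's canonical CSV layouts:
#' \describe{
#'   \item{`"spectrum"`}{columns `wavelength_nm,intensity`; optional `kind`
#'     column (constant) and `# key: value` header comments become metadata.}
#'   \item{`"titration"`}{columns `ligand_conc_M,F` with optional
#'     `A_ex,A_em`; `# protein_conc_M:` and `# tau_s:` header comments set
#'     the protein concentration and fluorophore lifetime.}
#'   \item{`"melt"`}{columns `temperature_C,signal`, optional
#'     `wavelength_nm` column or header comment.}
#'   \item{`"cd"`}{like `"spectrum"` but returns a [cd_spectrum()];
#'     header comments `units`, `mrw`, `conc_g_L`, `path_cm` are honoured.}
#' }
#' Rows are normalised to increasing x where the schema allows reordering
#' (spectra, melts); titration concentrations must already be strictly
#' increasing and are never silently reordered.
#'
#' @param path file path of a UTF-8 CSV with exact header names.
#' @param schema one of `"spectrum"`, `"titration"`, `"melt"`, `"cd"`.
#' @return A [spectrum()], [cd_spectrum()], [quench_titration()] or
#'   [melt_curve()] according to `schema`.
#' @export
read_table <- function(path, schema = c("spectrum", "titration", "melt", "cd")) {
  schema <- match.arg(schema)
  parsed <- read_csv_with_comments(path)
  df <- parsed$df; meta <- parsed$meta
  switch(schema,
    spectrum = {
      require_columns(df, c("wavelength_nm", "intensity"), path)
      x <- check_numeric_column(df, "wavelength_nm", path)
      y <- check_numeric_column(df, "intensity", path)
      o <- order(x)
      if (anyDuplicated(x))
        stop("validation error: duplicated wavelength values in ", path,
             call. = FALSE)
      kind <- if ("kind" %in% names(df)) unique(df$kind)[1L]
              else if (!is.null(meta$kind)) meta$kind else "emission"
      meta$kind <- NULL
      spectrum(x[o], y[o], kind = kind, meta = meta)
    },
    cd = {
      require_columns(df, c("wavelength_nm", "intensity"), path)
      x <- check_numeric_column(df, "wavelength_nm", path)
      y <- check_numeric_column(df, "intensity", path)
      if (anyDuplicated(x))
        stop("validation error: duplicated wavelength values in ", path,
             call. = FALSE)
      o <- order(x)
      cd_spectrum(x[o], y[o],
                  units = if (!is.null(meta$units)) meta$units else "mdeg",
                  mrw = if (!is.null(meta$mrw)) meta$mrw else 117.53,
                  conc = meta$conc_g_L,
                  path = if (!is.null(meta$path_cm)) meta$path_cm else 0.2)
    },
    titration = {
      require_columns(df, c("ligand_conc_M", "F"), path)
      conc <- check_numeric_column(df, "ligand_conc_M", path)
      F <- check_numeric_column(df, "F", path)
      if (any(diff(conc) <= 0))
        stop("validation error: ligand_conc_M must be strictly increasing in ",
             path, call. = FALSE)
      quench_titration(
        conc, F,
        A_ex = if ("A_ex" %in% names(df)) check_numeric_column(df, "A_ex", path) else 0,
        A_em = if ("A_em" %in% names(df)) check_numeric_column(df, "A_em", path) else 0,
        protein_conc = if (!is.null(meta$protein_conc_M)) meta$protein_conc_M else 1e-6,
        tau = if (!is.null(meta$tau_s)) meta$tau_s else 5e-9,
        corrected = isTRUE(meta$corrected == "true") || isTRUE(meta$corrected == TRUE))
    },
    melt = {
      require_columns(df, c("temperature_C", "signal"), path)
      tem <- check_numeric_column(df, "temperature_C", path)
      sig <- check_numeric_column(df, "signal", path)
      if (anyDuplicated(tem))
        stop("validation error: duplicated temperatures in ", path, call. = FALSE)
      o <- order(tem)
      wl <- if ("wavelength_nm" %in% names(df)) df$wavelength_nm[1L]
            else if (!is.null(meta$wavelength_nm)) meta$wavelength_nm else 210
      melt_curve(tem[o], sig[o], wavelength = as.numeric(wl))
    })
}

#' Write a spectroscopy object to its canonical CSV schema
#'
#' The inverse of [read_table()]: numeric content round-trips to better
#' than 1e-12 relative (values are written with 17 significant digits).
#'
#' @param x a `spectrum`, `cd_spectrum`, `quench_titration` or `melt_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) UseMethod("write_table")

write_body <- function(df, path, header_lines = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines(paste(names(df), collapse = ","), con)
  rows <- do.call(paste, c(lapply(df, function(v)
    if (is.numeric(v)) formatC(v, digits = 17, format = "g") else as.character(v)),
    sep = ","))
  writeLines(rows, con)
  invisible(path)
}

#' @export
write_table.spectrum <- function(x, path) {
  hdr <- c(sprintf("# kind: %s", x$kind),
           vapply(names(x$meta), function(k) sprintf("# %s: %s", k, x$meta[[k]]), ""))
  write_body(data.frame(wavelength_nm = x$wavelength, intensity = x$intensity),
             path, hdr)
}

#' @export
write_table.cd_spectrum <- function(x, path) {
  hdr <- c("# kind: cd",
           sprintf("# units: %s", x$units),
           sprintf("# mrw: %.17g", x$mrw),
           if (!is.null(x$conc)) sprintf("# conc_g_L: %.17g", x$conc),
           if (!is.null(x$path)) sprintf("# path_cm: %.17g", x$path))
  write_body(data.frame(wavelength_nm = x$wavelength, intensity = x$intensity),
             path, hdr)
}

#' @export
write_table.quench_titration <- function(x, path) {
  hdr <- c(sprintf("# protein_conc_M: %.17g", x$protein_conc),
           sprintf("# tau_s: %.17g", x$tau),
           sprintf("# corrected: %s", tolower(as.character(x$corrected))))
  write_body(data.frame(ligand_conc_M = x$ligand_conc, F = x$F,
                        A_ex = x$A_ex, A_em = x$A_em), path, hdr)
}

#' @export
write_table.melt_curve <- function(x, path) {
  write_body(data.frame(temperature_C = x$temperature, signal = x$signal),
             path, sprintf("# wavelength_nm: %.17g", x$wavelength))
}

#' Read a minimal JCAMP-DX spectrum
#'
#' Supports single-block files with `##XYDATA=(X++(Y..Y))` records in plain
#' AFFN form (no DIF/DUP compression), honouring `XFACTOR`, `YFACTOR`,
#' `FIRSTX`, `LASTX`, `NPOINTS`, `XUNITS` and `YUNITS`. Wavelengths are
#' validated to match `FIRSTX`/`LASTX`/`NPOINTS` when those are present.
#'
#' @param path JCAMP-DX file path.
#' @param kind spectrum kind tag for the returned object.
#' @return A [spectrum()].
#' @export
read_jcamp <- function(path, kind = "emission") {
  lines <- readLines(path, warn = FALSE)
  hdr <- function(key) {
    i <- grep(sprintf("^##%s\\s*=", key), lines, ignore.case = TRUE)
    if (!length(i)) return(NULL)
    trimws(sub("^##[^=]+=", "", lines[i[1L]]))
  }
  xf <- hdr("XFACTOR"); xf <- if (is.null(xf)) 1 else as.numeric(xf)
  yf <- hdr("YFACTOR"); yf <- if (is.null(yf)) 1 else as.numeric(yf)
  start <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA block in ", path, call. = FALSE)
  form <- toupper(gsub("\\s", "", sub("^##XYDATA=", "", lines[start[1L]],
                                      ignore.case = TRUE)))
  if (form != "(X++(Y..Y))")
    stop("unsupported XYDATA form: ", form, call. = FALSE)
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start[1L]]
  body <- lines[(start[1L] + 1L):(if (length(stop_at)) stop_at[1L] - 1L else length(lines))]
  body <- body[nzchar(trimws(body))]
  xs <- numeric(0); ys <- numeric(0)
  for (ln in body) {
    tok <- as.numeric(strsplit(trimws(ln), "[,[:space:]]+")[[1L]])
    if (anyNA(tok)) stop("non-numeric token in XYDATA of ", path, call. = FALSE)
    if (length(tok) < 2L) next
    x0 <- tok[1L] * xf
    yv <- tok[-1L] * yf
    # x of j-th y on this line interpolates toward next line's abscissa
    xs <- c(xs, x0 + seq_along(yv) - 1)  # provisional, fixed below if FIRSTX/LASTX given
    ys <- c(ys, yv)
  }
  np <- hdr("NPOINTS"); fx <- hdr("FIRSTX"); lx <- hdr("LASTX")
  if (!is.null(np) && as.integer(np) != length(ys))
    stop(sprintf("NPOINTS (%s) disagrees with data (%d points)", np, length(ys)),
         call. = FALSE)
  if (!is.null(fx) && !is.null(lx)) {
    xs <- seq(as.numeric(fx) * xf, as.numeric(lx) * xf, length.out = length(ys))
  }
  meta <- list()
  if (!is.null(hdr("XUNITS"))) meta$xunits <- hdr("XUNITS")
  if (!is.null(hdr("YUNITS"))) meta$yunits <- hdr("YUNITS")
  o <- order(xs)
  spectrum(xs[o], ys[o], kind = kind, meta = meta)
}
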