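# Flat-file formats.
#
# Feature tables are tab-separated with one row per feature and the XIC
# encoded as semicolon-separated "cycle:intensity" pairs:
#   SCPF:     scpf_id  parent_feature_id  charge  neutral_mass  mz  window_id  k  xic
#   fragment: frag_id  window_id  charge  neutral_mass  k  xic
# Pseudo spectra use msalign-style blocks (BEGIN IONS ... END IONS) with
# KEY=value headers and "mass<TAB>intensity<TAB>charge" ion lines.

.encode_xic <- function(x) {
  s <- x$support
  paste(sprintf("%d:%.10g", s, x$values[s]), collapse = ";")
}

.decode_xic <- function(str, k) {
  if (is.na(str) || !nzchar(str)) stop("empty XIC field")
  parts <- strsplit(str, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  cyc <- as.integer(vapply(kv, `[`, character(1), 1L))
  int <- as.numeric(vapply(kv, `[`, character(1), 2L))
  if (any(is.na(cyc)) || any(is.na(int))) stop("malformed XIC field")
  build_xic(cyc, int, k)
}

#' Read a feature table
#'
#' Parses a tab-separated SCPF or fragment-feature table (the format
#' written by \code{\link{write_feature_table}}; see the package README).
#' All XICs are expanded to a common length \code{k}: the maximum of the
#' table's \code{k} column, or the largest observed cycle index when that
#' column is absent. Rows violating a field invariant are rejected with
#' their row number.
#'
#' @param path File path.
#' @param kind \code{"scpf"} or \code{"fragment"}.
#' @return A list of \code{\link{scpf}} or \code{\link{fragment_feature}}
#'   objects.
#' @export
read_feature_table <- function(path, kind = c("scpf", "fragment")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- if (kind == "scpf")
    c("scpf_id", "parent_feature_id", "charge", "neutral_mass", "mz",
      "window_id", "xic")
  else c("frag_id", "window_id", "charge", "neutral_mass", "xic")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("feature table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  mass <- suppressWarnings(as.numeric(df$neutral_mass))
  if (any(is.na(mass)))
    stop(sprintf("non-numeric neutral_mass in row %s",
                 which(is.na(mass))[1]))
  k <- if ("k" %in% names(df)) {
    max(as.integer(df$k))
  } else {
    max(vapply(df$xic, function(s) {
      max(as.integer(sub(":.*", "", strsplit(s, ";", fixed = TRUE)[[1]])))
    }, integer(1)))
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch({
      x <- .decode_xic(df$xic[i], k)
      if (kind == "scpf")
        scpf(df$scpf_id[i], df$parent_feature_id[i],
             as.integer(df$charge[i]), mass[i], as.numeric(df$mz[i]), x,
             window_id = df$window_id[i])
      else
        fragment_feature(df$frag_id[i], df$window_id[i], mass[i],
                         as.integer(df$charge[i]), x)
    }, error = function(e)
      stop(sprintf("row %d: %s", i, conditionMessage(e)), call. = FALSE))
    out[[i]] <- rec
  }
  out
}

#' Write a feature table
#'
#' Serializes SCPFs or fragment features to the tab-separated format read
#' by \code{\link{read_feature_table}}. Number formatting is fixed so that
#' identical inputs yield byte-identical files.
#'
#' @param features List of \code{\link{scpf}} or
#'   \code{\link{fragment_feature}} objects.
#' @param path Output path.
#' @param kind \code{"scpf"} or \code{"fragment"}.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(features, path,
                                kind = c("scpf", "fragment")) {
  kind <- match.arg(kind)
  if (kind == "scpf") {
    header <- "scpf_id\tparent_feature_id\tcharge\tneutral_mass\tmz\twindow_id\tk\txic"
    lines <- vapply(features, function(f)
      sprintf("%s\t%s\t%d\t%.6f\t%.6f\t%s\t%d\t%s",
              f$scpf_id, f$parent_feature_id, f$charge, f$neutral_mass,
              f$mz, f$window_id, f$xic$k, .encode_xic(f$xic)),
      character(1))
  } else {
    header <- "frag_id\twindow_id\tcharge\tneutral_mass\tk\txic"
    lines <- vapply(features, function(f)
      sprintf("%s\t%s\t%d\t%.6f\t%d\t%s",
              f$frag_id, f$window_id, f$charge, f$neutral_mass,
              f$xic$k, .encode_xic(f$xic)),
      character(1))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write pseudo spectra to an msalign-style file
#'
#' One BEGIN IONS / END IONS block per spectrum with KEY=value headers
#' (ID, SCPF_ID, WINDOW_ID, RT_RANGE, PRECURSOR_MASS, PRECURSOR_CHARGE,
#' PRECURSOR_INTENSITY) followed by one "mass<TAB>intensity<TAB>charge"
#' line per fragment. Masses are printed with five decimal places.
#'
#' @param spectra List of \code{\link{pseudo_spectrum}} objects.
#' @param path Output path.
#' @param drop_empty Omit spectra with no assigned fragments.
#' @return \code{path}, invisibly.
#' @export
write_pseudo_spectra <- function(spectra, path, drop_empty = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    if (drop_empty && nrow(sp$fragments) == 0L) next
    writeLines(c(
      "BEGIN IONS",
      sprintf("ID=%s", sp$spectrum_id),
      sprintf("SCPF_ID=%s", sp$scpf_id),
      sprintf("WINDOW_ID=%s", sp$window_id),
      sprintf("RT_RANGE=%.4f,%.4f", sp$rt_range[1], sp$rt_range[2]),
      sprintf("PRECURSOR_MASS=%.5f", sp$precursor_mass),
      sprintf("PRECURSOR_CHARGE=%d", sp$precursor_charge),
      sprintf("PRECURSOR_INTENSITY=%.4f", sp$precursor_intensity)), con)
    if (nrow(sp$fragments))
      writeLines(sprintf("%.5f\t%.4f\t%d", sp$fragments$mass,
                         sp$fragments$intensity, sp$fragments$charge), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Parse an msalign-style pseudo-spectrum file
#'
#' Block parser for the format written by \code{\link{write_pseudo_spectra}}.
#' Fragment-feature ids are not stored in the file, so parsed fragments get
#' synthetic ids \code{<spectrum_id>.<n>}.
#'
#' @param path File path.
#' @return A list of \code{\link{pseudo_spectrum}} objects.
#' @export
read_pseudo_spectra <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends))
    stop("unbalanced BEGIN IONS / END IONS blocks")
  lapply(seq_along(starts), function(b) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, `[`, character(1), 2L)
    get <- function(k) vals[match(k, keys)]
    ion_lines <- block[!hdr & nzchar(block)]
    frags <- if (length(ion_lines)) {
      m <- do.call(rbind, strsplit(ion_lines, "\t", fixed = TRUE))
      data.frame(frag_id = sprintf("%s.%d", get("ID"), seq_len(nrow(m))),
                 mass = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]),
                 charge = as.integer(m[, 3]), stringsAsFactors = FALSE)
    } else NULL
    rt <- as.numeric(strsplit(get("RT_RANGE"), ",", fixed = TRUE)[[1]])
    pseudo_spectrum(get("ID"), get("SCPF_ID"),
                    as.numeric(get("PRECURSOR_MASS")),
                    as.integer(get("PRECURSOR_CHARGE")),
                    as.numeric(get("PRECURSOR_INTENSITY")),
                    get("WINDOW_ID"), rt, frags)
  })
}

#' Read a centroided peak-list table
#'
#' Parses a tab-separated peak list (columns \code{scan}, \code{ms_level},
#' \code{retention_time}, \code{cycle}, \code{window}, \code{mz},
#' \code{intensity}; one row per peak) into centroided spectra grouped by
#' scan.
#'
#' @param path File path.
#' @return A list of \code{\link{centroid_spectrum}} objects in file order.
#' @export
read_peak_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scan", "ms_level", "retention_time", "cycle", "window",
            "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("peak list missing column(s): %s",
                 paste(miss, collapse = ", ")))
  lapply(split(df, factor(df$scan, levels = unique(df$scan))), function(d) {
    centroid_spectrum(d$scan[1], d$ms_level[1], d$retention_time[1],
                      d$cycle[1],
                      data.frame(mz = d$mz, intensity = d$intensity),
                      window_id = as.character(d$window[1]))
  })
}

#' Write a centroided peak-list table
#'
#' @param spectra List of \code{\link{centroid_spectrum}} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_peak_list <- function(spectra, path) {
  rows <- lapply(spectra, function(sp) {
    if (nrow(sp$peaks) == 0L) return(character(0))
    sprintf("%s\t%d\t%.4f\t%d\t%s\t%.6f\t%.10g", sp$scan_id, sp$ms_level,
            sp$retention_time, sp$cycle_index, sp$window_id,
            sp$peaks$mz, sp$peaks$intensity)
  })
  writeLines(c("scan\tms_level\tretention_time\tcycle\twindow\tmz\tintensity",
               unlist(rows)), path)
  invisible(path)
}

#' Persist a fitted pair-scoring model
#'
#' Writes the logistic model as a flat key-value text file: one
#' \code{weight.<feature>} line per coefficient, the intercept, the feature
#' order, and the score cutoff it was selected with.
#'
#' @param model A \code{\link{train_pair_model}} fit.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pair_model <- function(model, path) {
  stopifnot(inherits(model, "pair_model"))
  w <- coef(model)
  lines <- c(sprintf("feature_order=%s",
                     paste(model$features, collapse = ",")),
             sprintf("bias=%.12g", w[["(Intercept)"]]),
             sprintf("weight.%s=%.12g", model$features,
                     w[model$features]))
  writeLines(lines, path)
  invisible(path)
}

#' Load a pair-scoring model written by \code{\link{write_pair_model}}
#'
#' @param path File path.
#' @return A minimal \code{"pair_model"} object usable for scoring
#'   (weights and bias only; no training metrics).
#' @export
read_pair_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  features <- strsplit(vals[keys == "feature_order"], ",")[[1]]
  bias <- as.numeric(vals[keys == "bias"])
  w <- as.numeric(vals[match(paste0("weight.", features), keys)])
  names(w) <- features
  structure(list(weights = w, bias = bias, features = features,
                 fit = NULL, metrics = NULL), class = "pair_model")
}
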