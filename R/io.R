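# Delimited-text readers/writers.  Comma-separated, header row, UTF-8,
# "." decimal.  Densities written to 4 dp, EAF to 4 dp, ppm errors to 3 dp.

FRACTION_COLUMNS <- c("sample_id", "replicate_id", "marker", "label",
                      "fraction_index", "density_g_ml", "copies",
                      "below_detection")

#' Read a gradient fraction table
#'
#' Reads a delimited fraction table (columns `sample_id`, `replicate_id`,
#' `marker`, `label`, `fraction_index`, `density_g_ml`, `copies`,
#' `below_detection`) and groups rows into [GradientProfile-class] objects
#' by sample, marker, label and replicate.
#'
#' @param path file path.
#' @return Named list of [GradientProfile-class] objects.
#' @seealso [writeFractionTable()]
#' @export
readFractionTable <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(FRACTION_COLUMNS, names(x))
  if (length(missing))
    stop("parse error: missing column(s): ", paste(missing, collapse = ", "))
  if (any(x$copies < 0))
    stop("parse error: negative copies at row(s) ",
         paste(which(x$copies < 0), collapse = ", "))
  grp <- interaction(x$sample_id, x$marker, x$label, x$replicate_id,
                     drop = TRUE, sep = "|")
  out <- lapply(split(x, grp), function(g) {
    if (anyDuplicated(g$fraction_index))
      stop("parse error: duplicate fraction index in profile ",
           g$sample_id[1], "/", g$marker[1], "/", g$label[1], "/",
           g$replicate_id[1])
    GradientProfile(g$sample_id[1], g$marker[1], g$label[1],
                    data.frame(fraction_index = g$fraction_index,
                               density = g$density_g_ml,
                               copies = g$copies,
                               below_detection = as.logical(g$below_detection)),
                    replicateId = g$replicate_id[1])
  })
  out[order(names(out))]
}

#' Write gradient profiles as a fraction table
#'
#' @param profiles a [GradientProfile-class] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFractionTable <- function(profiles, path) {
  if (is(profiles, "GradientProfile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    fr <- fractions(p)
    data.frame(sample_id = sampleId(p), replicate_id = replicateId(p),
               marker = markerGene(p), label = labelState(p),
               fraction_index = fr$fraction_index,
               density_g_ml = round(fr$density, 4),
               copies = fr$copies,
               below_detection = fr$below_detection)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column peak list
#'
#' Expects numeric columns `mz` and `intensity`.  Peaks are returned sorted
#' by m/z; peaks outside the 95-1000 Da acquisition window are retained but
#' flagged `in_window = FALSE`.  An empty file yields an empty list with a
#' warning.
#'
#' @param path file path.
#' @return `data.frame` with columns `mz`, `intensity`, `in_window`.
#' @export
readPeakList <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(x)))
    stop("parse error: peak list needs 'mz' and 'intensity' columns")
  if (nrow(x) == 0) {
    warning("empty peak list: ", path)
    return(data.frame(mz = numeric(), intensity = numeric(),
                      in_window = logical()))
  }
  if (!is.numeric(x$mz) || !is.numeric(x$intensity))
    stop("parse error: non-numeric values in peak list ", path)
  x <- x[order(x$mz), c("mz", "intensity"), drop = FALSE]
  x$in_window <- x$mz >= MASS_WINDOW[1] & x$mz <= MASS_WINDOW[2]
  rownames(x) <- NULL
  x
}

#' Write a peak list
#'
#' @param peaks `data.frame` with columns `mz`, `intensity`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePeakList <- function(peaks, path) {
  write.csv(peaks[c("mz", "intensity")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write an EAF result table
#'
#' One row per labeled/unlabeled pairing plus a `summary` row carrying the
#' mean (and clipped mean) across pairs.
#'
#' @param result an [EafResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEafResult <- function(result, path) {
  p <- eafPairs(result)
  num <- c("W_light", "W_lab", "dW")
  p[num] <- lapply(p[num], round, 4)
  p[c("eaf", "atom_pct")] <- lapply(p[c("eaf", "atom_pct")], round, 4)
  p[c("G", "M_light", "M_lab", "M_heavymax")] <-
    lapply(p[c("G", "M_light", "M_lab", "M_heavymax")], round, 4)
  p$row_type <- "pair"
  s <- eafSummary(result)
  srow <- p[1, ]
  srow[] <- NA
  srow$replicateId <- "all"
  srow$eaf <- round(s$mean, 4)
  srow$atom_pct <- round(100 * s$mean, 4)
  srow$row_type <- "summary"
  write.csv(rbind(p, srow), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the assignment table of a DOM sample
#'
#' @param sample a [DomSample-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAssignments <- function(sample, path) {
  a <- assignments(sample)
  a$error_ppm <- round(a$error_ppm, 3)
  a$ai_mod <- round(a$ai_mod, 4)
  a$rel_intensity <- round(a$rel_intensity, 8)
  cols <- c("mz", "intensity", "c", "h", "o", "n", "s", "p", "error_ppm",
            "ai_mod", "compound_class", "ambiguous", "rel_intensity")
  write.csv(a[cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write a samples-by-formulas relative intensity matrix
#'
#' The table has a `sample_id` first column; remaining columns are formula
#' keys like `C6H12O6N0S0P0`.
#'
#' @param path file path.
#' @return For `readSampleMatrix`, a numeric matrix with samples as rows.
#' @export
readSampleMatrix <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "sample_id")
    stop("parse error: first column must be 'sample_id'")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

#' @rdname readSampleMatrix
#' @param m samples-by-formulas matrix (rows summing to one).
#' @export
writeSampleMatrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a square labeled dissimilarity matrix
#'
#' @param d square dissimilarity matrix.
#' @param path output file path.
#' @export
writeDissimilarity <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), round(d, 6),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ordination as long-format coordinates plus eigenvalues
#'
#' @param ord result of [principalCoordinates()].
#' @param coordPath,eigPath output file paths.
#' @export
writeOrdination <- function(ord, coordPath, eigPath) {
  co <- ord$coordinates
  long <- data.frame(
    sample_id = rep(rownames(co), times = max(ncol(co), 0)),
    axis = rep(colnames(co), each = nrow(co)),
    coordinate = round(as.vector(co), 8))
  write.csv(long, coordPath, row.names = FALSE, quote = FALSE)
  eig <- data.frame(axis = seq_along(ord$eigenvalues),
                    eigenvalue = round(ord$eigenvalues, 8))
  eig$proportion_explained <- NA_real_
  k <- length(ord$proportionExplained)
  if (k) eig$proportion_explained[seq_len(k)] <-
      round(ord$proportionExplained, 8)
  write.csv(eig, eigPath, row.names = FALSE, quote = FALSE)
  invisible(c(coordPath, eigPath))
}
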