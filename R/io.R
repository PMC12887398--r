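# Plain-text readers and writers for every pipeline artifact: delimited
# titration/melt/shift tables with '#' metadata headers, the PLUMED-style
# HILLS and COLVAR dialects, gridded FES text, and single/multi-model PDB
# via bio3d.

.write_meta <- function(path, meta, df, col.names = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 15)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
}

.read_meta <- function(path) {
  lines <- readLines(path)
  ml <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in ml) {
    kv <- sub("^#\\s*", "", l)
    i <- regexpr(":", kv)
    if (i > 0) meta[[trimws(substr(kv, 1, i - 1))]] <-
        trimws(substr(kv, i + 1, nchar(kv)))
  }
  meta
}

#' Write / read a titration series
#'
#' Tab-delimited `(conc_nM, observable)` with `#`-prefixed metadata
#' (probe concentration, observable kind).
#'
#' @param series a [titration_series()].
#' @param path file path.
#' @return `read_titration` returns a [titration_series()].
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  .write_meta(path, list(probe_total_nM = series$probe_total,
                         obs_kind = series$obs_kind),
              data.frame(conc_nM = series$titrant_concs,
                         observable = series$observables))
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  meta <- .read_meta(path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  titration_series(df$conc_nM, df$observable,
                   as.numeric(meta$probe_total_nM),
                   meta$obs_kind %||% "anisotropy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read melt curves
#'
#' Tab-delimited `(temp_C, fluorescence)` plus a `condition` column when
#' several curves share one file.
#'
#' @param curves a [melt_curve()] or list of them.
#' @param path file path.
#' @return `read_melt` returns a list of [melt_curve()]s.
#' @export
write_melt <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cu)
    data.frame(temp_C = cu$temps, fluorescence = cu$signal,
               condition = if (nzchar(cu$condition)) cu$condition else "-")))
  .write_meta(path, list(n_curves = length(curves)), df)
  invisible(path)
}

#' @rdname write_melt
#' @export
read_melt <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = c("numeric", "numeric", "character"))
  lapply(split(df, factor(df$condition, levels = unique(df$condition))),
         function(d) melt_curve(d$temp_C, d$fluorescence,
                                if (d$condition[1] == "-") "" else d$condition[1]))
}

#' Write / read amide shift tables
#'
#' Tab-delimited `(residue_id, residue_name, dH_ppm, dN_ppm, state)`;
#' several states may share one file.
#'
#' @param tables a [shift_table()] or list of them.
#' @param path file path.
#' @return `read_shift_tables` returns a list of [shift_table()]s in file
#'   order.
#' @export
write_shift_tables <- function(tables, path) {
  if (inherits(tables, "shift_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(t)
    data.frame(residue_id = t$residue_id, residue_name = t$residue_name,
               dH_ppm = t$dH_ppm, dN_ppm = t$dN_ppm,
               state = attr(t, "state"))))
  .write_meta(path, list(n_states = length(tables)), df)
  invisible(path)
}

#' @rdname write_shift_tables
#' @export
read_shift_tables <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = c("integer", "character", "numeric",
                                  "numeric", "character"))
  lapply(split(df, factor(df$state, levels = unique(df$state))),
         function(d) shift_table(d$residue_id, d$residue_name, d$dH_ppm,
                                 d$dN_ppm, state = d$state[1]))
}

#' Write / read a hills log in the HILLS text dialect
#'
#' `#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf` header, one
#' record per line, full double precision (the log must reproduce the
#' deposited bias exactly).
#'
#' @param hills a [hills_log()].
#' @param path file path.
#' @return `read_hills` returns a [hills_log()].
#' @export
write_hills <- function(hills, path) {
  stopifnot(inherits(hills, "hills_log"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf", con)
  if (nrow(hills) > 0L)
    writeLines(sprintf("%.10g %.17g %.17g %.17g %.17g %.17g %.10g",
                       hills$time, hills$cv1, hills$cv2, hills$sigma_cv1,
                       hills$sigma_cv2, hills$height, hills$biasf), con)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#!", lines, value = TRUE)
  if (!length(hdr) || !grepl("FIELDS", hdr[1]))
    stop("not a HILLS-dialect file: missing '#! FIELDS' header")
  dat <- lines[!grepl("^#", lines)]
  if (!length(dat)) return(.empty_hills())
  m <- do.call(rbind, lapply(strsplit(trimws(dat), "\\s+"), as.numeric))
  hills_log(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6], m[, 7])
}

#' Write / read a collective-variable trace in the COLVAR dialect
#'
#' `#! FIELDS time rmsd cn` header, one frame per line.
#'
#' @param cv data.frame with columns `time` (or `frame`), `rmsd`, `cn`.
#' @param path file path.
#' @return `read_colvar` returns a data.frame `(time, rmsd, cn)`.
#' @export
write_colvar <- function(cv, path) {
  time <- if ("time" %in% names(cv)) cv$time else cv$frame
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time rmsd cn", con)
  writeLines(sprintf("%.10g %.10g %.10g", time, cv$rmsd, cv$cn), con)
  invisible(path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  dat <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(dat), "\\s+"), as.numeric))
  data.frame(time = m[, 1], rmsd = m[, 2], cn = m[, 3])
}

#' Write / read a gridded free-energy surface
#'
#' Long-format text `(cv1, cv2, free_energy_kcal)`, cv2 fastest.
#'
#' @param fes a `fes_grid_2d`.
#' @param path file path.
#' @return `read_fes` returns a `fes_grid_2d`.
#' @export
write_fes <- function(fes, path) {
  stopifnot(inherits(fes, "fes_grid_2d"))
  df <- data.frame(cv1 = rep(fes$cv1, each = length(fes$cv2)),
                   cv2 = rep(fes$cv2, length(fes$cv1)),
                   free_energy_kcal = as.vector(t(fes$F_kcal)))
  .write_meta(path, list(gamma = fes$gamma), df)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  meta <- .read_meta(path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  cv1 <- unique(df$cv1); cv2 <- unique(df$cv2)
  F <- matrix(df$free_energy_kcal, length(cv2), length(cv1))
  structure(list(cv1 = cv1, cv2 = cv2, F_kcal = t(F),
                 gamma = as.numeric(meta$gamma)),
            class = "fes_grid_2d")
}

#' Write / read conformers as PDB
#'
#' Single-model PDB for one conformer; multi-model for a list (a toy
#' trajectory). The base-centroid pseudo-atom is written as atom `BC`.
#'
#' @param conf a [conformer()] or list of conformers sharing one topology.
#' @param path file path.
#' @return `read_conformer_pdb` returns a [conformer()] or list of them.
#' @export
write_conformer_pdb <- function(conf, path) {
  confs <- if (inherits(conf, "conformer")) list(conf) else conf
  seqs <- rna15_sequence()
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(confs) > 1L
  for (m in seq_along(confs)) {
    a <- confs[[m]]$atoms
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)), substr(a$atom, 1, 4), seqs[a$resid], a$resid,
      a$x, a$y, a$z, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_conformer_pdb
#' @export
read_conformer_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_model <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  build <- function(xyz_row) {
    m <- matrix(xyz_row, ncol = 3, byrow = TRUE)
    conformer(data.frame(atom = at$elety, resid = at$resno,
                         element = trimws(at$elesy), x = m[, 1], y = m[, 2],
                         z = m[, 3], stringsAsFactors = FALSE),
              label = basename(path))
  }
  if (n_model == 1L) build(as.vector(pdb$xyz))
  else lapply(seq_len(n_model), function(m) build(pdb$xyz[m, ]))
}
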