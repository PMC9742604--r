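# Readers and writers for the on-disk interchange formats: NIfTI volumes,
# tab-separated atlas / series / connectivity tables, flat key=value run
# configurations and md5 manifests. All TSVs carry a header row and ROI
# labels; coordinates are 0-based voxel indices.

#' Write / read a 4D volume as NIfTI
#'
#' @param volume 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `read_volume_nifti` returns a plain 4D array.
#' @export
write_volume_nifti <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  attributes(a) <- list(dim = dim(a))
  a
}

#' Write / read an atlas table
#'
#' Tab-separated with header `index name cx cy cz volume`.
#'
#' @param atlas atlas `data.frame`.
#' @param path file path.
#' @param grid,radius geometry reattached on read (TSV stores only the
#'   table).
#' @export
write_atlas_tsv <- function(atlas, path) {
  write.table(atlas[, c("index", "name", "cx", "cy", "cz", "volume")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(path, grid = NULL, radius = 2) {
  atlas <- read.delim(path, stringsAsFactors = FALSE)
  attr(atlas, "grid") <- grid
  attr(atlas, "radius") <- radius
  atlas
}

#' Write / read a labelled numeric matrix (series or connectivity)
#'
#' Tab-separated; the first column holds row labels, the header the column
#' labels. Values are written with full double precision so identical
#' computations give byte-identical files.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  rn <- rownames(m) %||% sprintf("R%03d", seq_len(nrow(m)))
  cn <- colnames(m) %||% (if (ncol(m) == nrow(m) && !is.null(rownames(m)))
    rownames(m) else sprintf("t%03d", seq_len(ncol(m))))
  df <- data.frame(label = rn, format(m, digits = 17, trim = TRUE,
                                      scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("label", cn)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write / read a flat key = value run configuration
#'
#' One `key = value` pair per line (TOML-style scalars; vectors are
#' comma-separated). Values round-trip losslessly for numerics (full
#' precision) and strings.
#'
#' @param config named list of scalars or atomic vectors.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v)) paste0('"', v, '"', collapse = ", ")
    else if (is.logical(v)) paste(ifelse(v, "true", "false"), collapse = ", ")
    else paste(format(v, digits = 17, trim = TRUE), collapse = ", ")
  }
  lines <- vapply(names(config), function(k) paste(k, "=", fmt(config[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  out <- list()
  for (ln in lines) {
    k <- trimws(sub("=.*", "", ln))
    v <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(v, ",")[[1]])
    if (all(grepl('^".*"$', parts))) {
      out[[k]] <- gsub('^"|"$', "", parts)
    } else if (all(parts %in% c("true", "false"))) {
      out[[k]] <- parts == "true"
    } else {
      out[[k]] <- as.numeric(parts)
    }
  }
  out
}

#' Write an md5 manifest for a set of files
#'
#' @param dir directory whose files are listed.
#' @param path manifest path (default `manifest.tsv` inside `dir`).
#' @export
write_manifest <- function(dir, path = file.path(dir, "manifest.tsv")) {
  files <- setdiff(list.files(dir, recursive = TRUE), basename(path))
  sums <- tools::md5sum(file.path(dir, files))
  write.table(data.frame(file = files, md5 = unname(sums)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Model checkpoints: parameters are plain nested lists of numerics, stored
# with saveRDS at run time.
#' Save / load a model checkpoint
#' @param model an `fbn_model`.
#' @param path checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
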