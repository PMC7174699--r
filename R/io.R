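#' @name netlesion-io
#' @title Delimited-text readers and writers
#' @description
#' All artifacts are plain text: connectomes as TSV numeric matrices with
#' region ids as row/column names, the atlas and impact tables as TSV with
#' header rows, ground truth and reports as JSON. Writers accept optional
#' `comment` lines (prefixed `#`) so pipeline outputs can carry their seed
#' and configuration hash; readers skip such lines.
NULL

write_lines_tsv <- function(df, path, comment = NULL, rownames = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = rownames, col.names = !is.null(colnames(df)) || !rownames)
  invisible(path)
}

#' @rdname netlesion-io
#' @param conn a [connectome]; @param path file path; @param comment optional
#'   header comment line(s).
#' @export
write_connectome <- function(conn, path, comment = NULL) {
  stopifnot(inherits(conn, "connectome"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(format(conn$weights, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname netlesion-io
#' @param atlas_ref atlas label attached to the read connectome.
#' @export
read_connectome <- function(path, atlas_ref = "file") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                                   comment.char = "#", check.names = FALSE))
  connectome(m, region_ids = as.integer(rownames(m)), atlas_ref = atlas_ref)
}

#' @rdname netlesion-io
#' @param atlas a `parcellation_atlas`.
#' @export
write_atlas <- function(atlas, path, comment = NULL) {
  write_lines_tsv(as.data.frame(atlas), path, comment)
}

#' @rdname netlesion-io
#' @export
read_atlas <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  structure(df, class = c("parcellation_atlas", "data.frame"))
}

#' @rdname netlesion-io
#' @param impacts an [impact_set].
#' @export
write_impacts <- function(impacts, path, comment = NULL) {
  stopifnot(inherits(impacts, "impact_set"))
  rm <- impacts$rmps
  colnames(rm) <- paste0("rmps_", colnames(rm))
  write_lines_tsv(cbind(impacts$cases, as.data.frame(rm)), path, comment)
}

#' @rdname netlesion-io
#' @export
read_impacts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  rcols <- grep("^rmps_", names(df))
  rm <- as.matrix(df[, rcols, drop = FALSE])
  colnames(rm) <- sub("^rmps_", "", colnames(rm))
  impact_set(df[, -rcols, drop = FALSE], rm)
}

#' @rdname netlesion-io
#' @param truth a [ground_truth].
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname netlesion-io
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(x$hub_ids, x$high_strain_ids, x$concussion_strain_shift,
               x$kinematic_strain_coupling, x$seed)
}

#' @rdname netlesion-io
#' @param importance a `node_importance`.
#' @export
write_importance <- function(importance, path, comment = NULL) {
  comment <- c(comment, paste0("provenance: ", attr(importance, "provenance") %||% "unknown"))
  write_lines_tsv(as.data.frame(importance), path, comment)
}

#' @rdname netlesion-io
#' @export
read_importance <- function(path) {
  first <- readLines(path, n = 2)
  prov <- sub("^# provenance: ", "", grep("^# provenance:", first, value = TRUE))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  structure(df, provenance = if (length(prov)) prov else "unknown",
            class = c("node_importance", "data.frame"))
}

#' @rdname netlesion-io
#' @param sweep a [lesion_sweep] result.
#' @export
write_sweep <- function(sweep, path, comment = NULL) {
  stopifnot(inherits(sweep, "deletion_sweep"))
  comment <- c(comment,
               sprintf("k: %d | subject: %s | ge_intact: %.17g | regions: %s",
                       sweep$k, sweep$subject_id, sweep$ge_intact,
                       paste(sweep$region_ids, collapse = ",")))
  write_lines_tsv(sweep$outcomes, path, comment)
}

#' @rdname netlesion-io
#' @export
read_sweep <- function(path) {
  hdr <- grep("^# k:", readLines(path, n = 5), value = TRUE)
  parts <- strsplit(sub("^# ", "", hdr), " \\| ")[[1]]
  val <- function(key) sub(paste0("^", key, ": "), "", grep(paste0("^", key, ":"), parts, value = TRUE))
  outcomes <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  structure(list(k = as.integer(val("k")), subject_id = val("subject"),
                 n_regions = length(strsplit(val("regions"), ",")[[1]]),
                 region_ids = as.integer(strsplit(val("regions"), ",")[[1]]),
                 ge_intact = as.numeric(val("ge_intact")), outcomes = outcomes),
            class = "deletion_sweep")
}
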