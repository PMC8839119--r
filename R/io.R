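# File formats. All artifacts are plain text: skeleton and matrix CSVs
# (comma-separated, '.' decimal, mandatory header, '# units: m' comment
# line), ascii PLY point clouds with a JSON sidecar for the anchor
# annotation, TSV trial metadata, JSON object frames, optional Newick
# dendrograms. Every writer's output is re-readable by the matching reader.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a skeleton sequence as CSV
#'
#' Long format with columns `trial_id, frame, joint, x, y, z`; 1-based
#' contiguous frames; the 13 canonical joints per frame in canonical order;
#' a `# units: m` comment line precedes the header. Coordinates are written
#' with 17 significant digits so a round trip is bit-exact.
#'
#' @param seq A `skeleton_sequence`.
#' @param path File path.
#' @return `write_skeleton_csv` returns `path` invisibly;
#'   `read_skeleton_csv` returns a `skeleton_sequence`.
#' @export
write_skeleton_csv <- function(seq, path) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  T_ <- dim(seq$frames)[1]
  df <- data.frame(
    trial_id = seq$trial_id,
    frame = rep(seq_len(T_), each = 13L),
    joint = rep(STS_JOINTS, times = T_),
    x = fmt_num(as.vector(t(seq$frames[, , 1]))),
    y = fmt_num(as.vector(t(seq$frames[, , 2]))),
    z = fmt_num(as.vector(t(seq$frames[, , 3])))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: m", paste(names(df), collapse = ",")), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_skeleton_csv
#' @param coordinate_frame Frame tag to attach to the sequence read
#'   (`"camera"` or `"object"`); the CSV itself does not carry it.
#' @export
read_skeleton_csv <- function(path, coordinate_frame = "camera") {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!identical(trimws(first), "# units: m")) {
    stop("skeleton CSV must declare '# units: m' on its first line: ", path)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("trial_id", "frame", "joint", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("skeleton CSV must have columns ", paste(need, collapse = ", "))
  }
  if (length(unique(df$trial_id)) != 1L) stop("skeleton CSV must hold one trial")
  bad_joint <- setdiff(unique(df$joint), STS_JOINTS)
  if (length(bad_joint) > 0L) {
    stop("unknown joint name: ", paste(bad_joint, collapse = ", "))
  }
  frames_seen <- sort(unique(df$frame))
  T_ <- length(frames_seen)
  if (!identical(frames_seen, seq_len(T_)) && !identical(as.integer(frames_seen), seq_len(T_))) {
    stop("frames must be contiguous and 1-based")
  }
  for (j in STS_JOINTS) {
    nj <- sum(df$joint == j)
    if (nj != T_) stop("missing joint '", j, "': ", nj, " of ", T_, " frames present")
  }
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad) > 0L) {
    stop("non-finite coordinate at data row ", bad[1])
  }
  arr <- array(0, dim = c(T_, 13, 3))
  ord <- order(df$frame, match(df$joint, STS_JOINTS))
  df <- df[ord, ]
  arr[, , 1] <- matrix(df$x, nrow = T_, ncol = 13, byrow = TRUE)
  arr[, , 2] <- matrix(df$y, nrow = T_, ncol = 13, byrow = TRUE)
  arr[, , 3] <- matrix(df$z, nrow = T_, ncol = 13, byrow = TRUE)
  skeleton_sequence(df$trial_id[1], arr, coordinate_frame)
}

#' Write / read an ascii PLY point cloud
#'
#' Minimal ascii PLY with `x`, `y`, `z` vertex properties (written as
#' `double`, read as `float` or `double`), in meters.
#'
#' @param points N x 3 matrix (m).
#' @param path File path.
#' @export
write_ply <- function(points, path) {
  P <- as_matrix3(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply",
    "format ascii 1.0",
    "comment units: m",
    sprintf("element vertex %d", nrow(P)),
    "property double x",
    "property double y",
    "property double z",
    "end_header"
  ), con)
  writeLines(paste(fmt_num(P[, 1]), fmt_num(P[, 2]), fmt_num(P[, 3])), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!identical(lines[1], "ply")) stop("not a PLY file: ", path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header has no end_header: ", path)
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header))) stop("only ascii PLY is supported")
  nv_line <- grep("^element vertex ", header, value = TRUE)
  if (length(nv_line) != 1L) stop("PLY must have exactly one vertex element")
  nv <- as.integer(sub("^element vertex ", "", nv_line))
  props <- sub("^property (float|double) ", "",
               grep("^property (float|double) ", header, value = TRUE))
  if (!identical(props[1:3], c("x", "y", "z"))) {
    stop("PLY vertex properties must start with x, y, z")
  }
  body <- lines[(end + 1):(end + nv)]
  vals <- utils::read.table(text = body)
  as_matrix3(vals[, 1:3], "PLY vertices")
}

#' Write / read a seat scan (patches plus anchor sidecar)
#'
#' The two patches go to `<name>_surface` and `<name>_reference` files (ascii
#' PLY by default, or headered CSV with `x,y,z` columns), and a JSON sidecar
#' `<name>_scan.json` carries the patch roles and file names, the annotated
#' anchor point (armrest/handrail base, camera frame, meters) and the seat
#' type. Reading fails if the sidecar lacks the anchor annotation.
#'
#' @param scan A `seat_scan`.
#' @param dir Directory for the scan files.
#' @param name File-name stem.
#' @param format `"ply"` or `"csv"` for the patch files.
#' @return `write_seat_scan` returns the sidecar path invisibly;
#'   `read_seat_scan` returns a `seat_scan` (with no generator ground truth).
#' @export
write_seat_scan <- function(scan, dir, name = "seat", format = c("ply", "csv")) {
  stopifnot(inherits(scan, "seat_scan"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- format
  surf_file <- paste0(name, "_surface.", ext)
  ref_file <- paste0(name, "_reference.", ext)
  write_patch <- function(pts, file) {
    if (format == "ply") {
      write_ply(pts, file.path(dir, file))
    } else {
      con <- file(file.path(dir, file), "w")
      on.exit(close(con))
      writeLines(c("# units: m", "x,y,z"), con)
      writeLines(paste(fmt_num(pts[, 1]), fmt_num(pts[, 2]), fmt_num(pts[, 3]),
                       sep = ","), con)
    }
  }
  write_patch(scan$surface_points, surf_file)
  write_patch(scan$reference_points, ref_file)
  sidecar <- file.path(dir, paste0(name, "_scan.json"))
  jsonlite::write_json(list(
    units = "m",
    seat_type = scan$seat_type,
    format = format,
    patches = list(surface = surf_file, reference = ref_file),
    anchor_point = scan$anchor_point
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_seat_scan
#' @param sidecar Path to the `_scan.json` sidecar.
#' @export
read_seat_scan <- function(sidecar) {
  if (!file.exists(sidecar)) stop("no such sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$anchor_point)) {
    stop("sidecar is missing the anchor_point annotation: ", sidecar)
  }
  if (length(meta$anchor_point) != 3L || !all(is.finite(meta$anchor_point))) {
    stop("anchor_point must be a finite 3-vector")
  }
  dir <- dirname(sidecar)
  read_patch <- function(file) {
    path <- file.path(dir, file)
    if (identical(meta$format, "csv")) {
      df <- utils::read.csv(path, comment.char = "#")
      as_matrix3(df[, c("x", "y", "z")], "scan CSV")
    } else {
      read_ply(path)
    }
  }
  structure(list(
    surface_points = read_patch(meta$patches$surface),
    reference_points = read_patch(meta$patches$reference),
    anchor_point = as.double(meta$anchor_point),
    seat_type = meta$seat_type %||% NA_character_,
    truth = NULL
  ), class = "seat_scan")
}

#' Write / read a labelled square matrix as CSV
#'
#' Used for `Dsum`, the per-joint `Dj` and any other trial-by-trial matrix;
#' trial ids form the header row and first column.
#'
#' @param M Square matrix with identical row and column names.
#' @param path File path.
#' @export
write_matrix_csv <- function(M, path) {
  stopifnot(is.matrix(M), !is.null(rownames(M)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("trial_id", colnames(M)), collapse = ","), con)
  for (i in seq_len(nrow(M))) {
    writeLines(paste(c(rownames(M)[i], fmt_num(M[i, ])), collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "double"
  M
}

#' Write / read trial metadata as TSV
#'
#' Columns `trial_id`, `participant_id`, `sex`, `BI`, `MMSE`, `product`
#' (plus any extras present, e.g. the planted `archetype` of synthetic
#' trials).
#'
#' @param metadata Data frame as produced by [study_metadata()].
#' @param path File path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "participant_id", "sex", "BI", "MMSE", "product")
  if (!all(need %in% names(df))) {
    stop("metadata TSV must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$trial_id)) stop("duplicate trial_id in metadata")
  df
}

#' Write / read an object frame as JSON
#'
#' Records the basis, rotation (row-major), origin and homogeneous transform
#' of an estimated object-centered frame for audit.
#'
#' @param frame An `object_frame`.
#' @param path File path.
#' @export
write_object_frame_json <- function(frame, path) {
  stopifnot(inherits(frame, "object_frame"))
  jsonlite::write_json(list(
    units = "m",
    ex = frame$ex, ey = frame$ey, ez = frame$ez,
    ex_raw = frame$ex_raw,
    R_row_major = as.vector(t(frame$R)),
    P0 = frame$P0,
    H_row_major = as.vector(t(frame$H))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_object_frame_json
#' @export
read_object_frame_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- list(ex = x$ex, ey = x$ey, ez = x$ez, ex_raw = x$ex_raw)
  make_transform(basis, x$P0)
}

#' Export a linkage tree
#'
#' `write_linkage_csv` writes the merge table (`child_a`, `child_b`,
#' `height`, `size`; negative children are leaves); `export_newick` writes
#' the dendrogram as a Newick tree with merge heights as node depths.
#'
#' @param tree A `linkage_tree`.
#' @param path File path.
#' @export
write_linkage_csv <- function(tree, path) {
  stopifnot(inherits(tree, "linkage_tree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("child_a,child_b,height,size", con)
  m <- tree$merges
  writeLines(paste(m$child_a, m$child_b, fmt_num(m$height), m$size, sep = ","),
             con)
  invisible(path)
}

#' @rdname write_linkage_csv
#' @export
export_newick <- function(tree, path) {
  stopifnot(inherits(tree, "linkage_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
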