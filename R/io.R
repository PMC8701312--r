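#' Read a per-vertex map from disk
#'
#' Supported dialects: FreeSurfer new-style binary morphometry (`curv`,
#' magic bytes 0xFF 0xFF 0xFF, big-endian IEEE-754 single precision), plain
#' CSV with a single `value` column, and GIFTI shape/functional XML with
#' ASCII-encoded data.
#'
#' @param path file path
#' @param format `"curv"`, `"csv"` or `"gifti"`; default guessed from the
#'   file extension
#' @param mesh optional `surface_mesh`; if supplied the declared vertex
#'   count is validated against it
#' @param unit unit tag to attach (sidecar JSON, if present, wins)
#' @return a `vertex_map`
#' @export
read_vertex_map <- function(path, format = NULL, mesh = NULL,
                            unit = "dimensionless") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) format <- guess_map_format(path)
  format <- match.arg(format, c("curv", "csv", "gifti"))
  values <- switch(format,
    curv = read_curv(path),
    csv = read_csv_map(path),
    gifti = read_gifti_shape(path)
  )
  side <- read_sidecar(path)
  if (!is.null(side$unit)) unit <- side$unit
  mesh_id <- if (!is.null(side$mesh_id)) side$mesh_id else "unbound"
  if (!is.null(mesh)) {
    if (length(values) != n_vertices(mesh)) {
      stop("format error: file declares ", length(values),
           " vertices but mesh has ", n_vertices(mesh))
    }
    mesh_id <- mesh$mesh_id
  }
  vertex_map(values, unit = unit, mesh = mesh_id)
}

#' Write a per-vertex map to disk
#'
#' Every writer also emits a `<path>.json` sidecar recording the unit tag,
#' the mesh id, and provenance (stage, parameters, seed).
#'
#' @param map a `vertex_map` (or bare numeric vector)
#' @param path destination path
#' @param format `"curv"`, `"csv"` or `"gifti"`
#' @param provenance optional named list merged into the sidecar
#' @return `path`, invisibly
#' @export
write_vertex_map <- function(map, path, format = NULL, provenance = list()) {
  if (is.null(format)) format <- guess_map_format(path)
  format <- match.arg(format, c("curv", "csv", "gifti"))
  values <- map_values(map)
  switch(format,
    curv = write_curv(values, path),
    csv = write_csv_map(values, path),
    gifti = write_gifti_shape(values, path)
  )
  meta <- list(
    unit = if (inherits(map, "vertex_map")) map$unit else "dimensionless",
    mesh_id = if (inherits(map, "vertex_map")) map$mesh_id else "unbound",
    format = format
  )
  write_sidecar(path, c(meta, provenance))
  invisible(path)
}

guess_map_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) return("csv")
  if (ext %in% c("gii", "gifti")) return("gifti")
  "curv"
}

# -- FreeSurfer curv (new-style) ---------------------------------------------

read_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  if (!identical(as.integer(magic), c(255L, 255L, 255L))) {
    stop("dialect error: not a new-style curv file (magic ",
         paste(sprintf("0x%02X", as.integer(magic)), collapse = " "), ")")
  }
  nv <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  readBin(con, "integer", n = 1L, size = 4L, endian = "big") # face count
  vpv <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (vpv != 1L) stop("dialect error: values-per-vertex ", vpv, " unsupported")
  vals <- readBin(con, "numeric", n = nv, size = 4L, endian = "big")
  if (length(vals) != nv) {
    stop("format error: header declares ", nv, " vertices but file holds ",
         length(vals))
  }
  vals
}

write_curv <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xFF, 0xFF, 0xFF)), con)
  writeBin(as.integer(length(values)), con, size = 4L, endian = "big")
  writeBin(0L, con, size = 4L, endian = "big")
  writeBin(1L, con, size = 4L, endian = "big")
  writeBin(as.numeric(values), con, size = 4L, endian = "big")
  invisible(path)
}

# -- CSV map (decimal, 9 significant digits) ---------------------------------

read_csv_map <- function(path) {
  df <- utils::read.csv(path)
  if (!"value" %in% names(df)) stop("format error: CSV map needs a 'value' column")
  if ("vertex" %in% names(df)) {
    idx <- df$vertex
    if (idx[1L] != 0L || !identical(as.integer(idx), seq.int(0L, length.out = nrow(df)))) {
      stop("format error: explicit 'vertex' index column must be 0-based and contiguous")
    }
  }
  as.numeric(df$value)
}

write_csv_map <- function(values, path) {
  utils::write.table(
    data.frame(value = sprintf("%.9g", values)),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- GIFTI shape (ASCII encoding) --------------------------------------------

read_gifti_shape <- function(path) {
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  if (inherits(da, "xml_missing")) stop("dialect error: no DataArray in GIFTI file")
  enc <- xml2::xml_attr(da, "Encoding")
  if (!identical(enc, "ASCII")) {
    stop("dialect error: GIFTI encoding '", enc, "' unsupported (ASCII only)")
  }
  n <- as.integer(xml2::xml_attr(da, "Dim0"))
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1L]])
  if (length(vals) != n) {
    stop("format error: GIFTI declares ", n, " values but holds ", length(vals))
  }
  vals
}

write_gifti_shape <- function(values, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = "NIFTI_INTENT_SHAPE", DataType = "NIFTI_TYPE_FLOAT32",
    ArrayIndexingOrder = "RowMajorOrder", Dimensionality = "1",
    Dim0 = as.character(length(values)), Encoding = "ASCII",
    Endian = "LittleEndian")
  xml2::xml_add_child(da, "Data", paste(sprintf("%.9g", values), collapse = " "))
  xml2::write_xml(doc, path)
  invisible(path)
}

# -- provenance sidecars -----------------------------------------------------

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

# -- cohort table ------------------------------------------------------------

#' Read a subject table
#'
#' Expects a delimited text file with one row per subject and columns
#' `subject_id, group, sex, age_t1, isi, fsiq, handedness` plus 43-item
#' behavioral responses per timepoint in columns `rbsr_t1_1 .. rbsr_t1_43`
#' and `rbsr_t2_1 .. rbsr_t2_43`. Group / sex / handedness are parsed
#' case-insensitively; item missingness is the empty field or `NA` (numeric
#' sentinels such as -999 are rejected since items live on the 0-3 scale).
#'
#' @param path CSV/TSV path
#' @param max_missing_items maximum missing items per timepoint per subject
#'   (default 3 of 43)
#' @return a `cohort` object: list with `subjects` data.frame and
#'   `rbsr_t1`, `rbsr_t2` item matrices (NA = missing)
#' @export
read_cohort_table <- function(path, max_missing_items = 3L) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  req <- c("subject_id", "group", "sex", "age_t1", "isi", "fsiq", "handedness")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("schema error: missing required column(s): ",
                         paste(miss, collapse = ", "))
  it1 <- paste0("rbsr_t1_", 1:43)
  it2 <- paste0("rbsr_t2_", 1:43)
  miss_it <- setdiff(c(it1, it2), names(df))
  if (length(miss_it)) stop("schema error: missing item column(s): ",
                            paste(utils::head(miss_it, 3), collapse = ", "),
                            if (length(miss_it) > 3) " ...")
  subjects <- data.frame(
    subject_id = as.character(df$subject_id),
    group = parse_level(df$group, c("ASD", "TD")),
    sex = parse_level(df$sex, c("male", "female")),
    age_t1 = as.numeric(df$age_t1),
    isi = as.numeric(df$isi),
    fsiq = as.numeric(df$fsiq),
    handedness = parse_level(df$handedness, c("right", "left")),
    stringsAsFactors = FALSE
  )
  as_cohort(subjects,
            rbsr_t1 = as.matrix(df[, it1]),
            rbsr_t2 = as.matrix(df[, it2]),
            max_missing_items = max_missing_items)
}

parse_level <- function(x, levels) {
  m <- match(tolower(trimws(as.character(x))), tolower(levels))
  if (anyNA(m)) {
    stop("validation error: unrecognized value(s) '",
         paste(unique(x[is.na(m)]), collapse = "', '"),
         "' (expected one of: ", paste(levels, collapse = ", "), ")")
  }
  factor(levels[m], levels = levels)
}

#' Assemble a cohort object
#'
#' @param subjects data.frame with subject_id, group, sex, age_t1, isi,
#'   fsiq, handedness
#' @param rbsr_t1,rbsr_t2 n x 43 item matrices (NA = missing)
#' @param max_missing_items per-timepoint missingness cap
#' @return a `cohort`
#' @export
as_cohort <- function(subjects, rbsr_t1 = NULL, rbsr_t2 = NULL,
                      max_missing_items = 3L) {
  n <- nrow(subjects)
  bad_isi <- which(!is.finite(subjects$isi) | subjects$isi <= 0)
  if (length(bad_isi)) {
    stop("validation error: non-positive interscan interval for subject(s): ",
         paste(subjects$subject_id[bad_isi], collapse = ", "))
  }
  bad_age <- which(!is.finite(subjects$age_t1) | subjects$age_t1 <= 0)
  if (length(bad_age)) {
    stop("validation error: non-positive age for subject(s): ",
         paste(subjects$subject_id[bad_age], collapse = ", "))
  }
  for (nm in c("rbsr_t1", "rbsr_t2")) {
    m <- get(nm)
    if (is.null(m)) next
    if (nrow(m) != n || ncol(m) != 43L) {
      stop("schema error: ", nm, " must be ", n, " x 43")
    }
    ok <- is.na(m) | (m >= 0 & m <= 3)
    if (!all(ok)) {
      stop("validation error: ", nm, " holds out-of-range item values ",
           "(items are 0-3; numeric missing sentinels are rejected)")
    }
    nmiss <- rowSums(is.na(m))
    over <- which(nmiss > max_missing_items)
    if (length(over)) {
      stop("validation error: more than ", max_missing_items,
           " missing items at ", nm, " for subject(s): ",
           paste(subjects$subject_id[over], collapse = ", "))
    }
  }
  structure(list(subjects = subjects, rbsr_t1 = rbsr_t1, rbsr_t2 = rbsr_t2,
                 max_missing_items = as.integer(max_missing_items)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("cohort:", nrow(x$subjects), "subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  if (!is.null(x$rbsr_t1)) {
    cat("  RBS-R items: T1 missing", sum(is.na(x$rbsr_t1)),
        "cells; T2 missing", sum(is.na(x$rbsr_t2)), "cells\n")
  }
  invisible(x)
}

#' Write a cohort table
#' @param cohort a `cohort`
#' @param path CSV destination
#' @return `path` invisibly
#' @export
write_cohort_table <- function(cohort, path) {
  df <- cohort$subjects
  t1 <- as.data.frame(cohort$rbsr_t1)
  names(t1) <- paste0("rbsr_t1_", 1:43)
  t2 <- as.data.frame(cohort$rbsr_t2)
  names(t2) <- paste0("rbsr_t2_", 1:43)
  utils::write.csv(cbind(df, t1, t2), path, row.names = FALSE, na = "")
  invisible(path)
}

# -- gene sets ---------------------------------------------------------------

#' Read gene sets (GMT or one-symbol-per-line)
#'
#' GMT lines are `name<TAB>annotation<TAB>member1<TAB>member2...`. A file
#' without tabs is treated as a single plain list named after the file.
#' Duplicate symbols within a set are collapsed with a warning; an empty
#' set is an error.
#'
#' @param path file path
#' @return named list of `gene_set` objects (fields `name`, `annotation`,
#'   `members`)
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("validation error: empty gene-set file")
  if (!any(grepl("\t", lines))) {
    nm <- tools::file_path_sans_ext(basename(path))
    return(stats::setNames(list(gene_set(nm, trimws(lines))), nm))
  }
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1L]]
    if (length(parts) < 3L) {
      stop("validation error: GMT line with no members: ", parts[1L])
    }
    gene_set(parts[1L], parts[-(1:2)], annotation = parts[2L])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Construct a gene set
#' @param name set name
#' @param members character vector of gene symbols
#' @param annotation free-text annotation (e.g. "downregulated")
#' @return a `gene_set`
#' @export
gene_set <- function(name, members, annotation = "") {
  members <- members[nzchar(members)]
  if (!length(members)) stop("validation error: empty gene set '", name, "'")
  if (anyDuplicated(members)) {
    warning("gene set '", name, "': ", sum(duplicated(members)),
            " duplicate symbol(s) collapsed")
    members <- unique(members)
  }
  structure(list(name = name, annotation = annotation, members = members),
            class = "gene_set")
}

#' Write gene sets in GMT format
#' @param sets list of `gene_set`
#' @param path destination
#' @return `path` invisibly
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$annotation)) s$annotation else "na",
            s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
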