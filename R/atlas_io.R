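# Reading and writing the package's external artifacts: expression atlases,
# probe annotations, gene lists, HECS database files and result tables.

#' Read an expression atlas from delimited text files
#'
#' An expression atlas is a non-negative intensity matrix of probes (rows) by
#' samples (columns), accompanied by a replicate map assigning each sample to a
#' cell type and a probe annotation table linking probes to Entrez gene ids and
#' gene symbols. Probes without annotation are retained: they take part in
#' expression-ranked test lists but can never enter a signature.
#'
#' @param matrix_path Path to the expression matrix. Tab-separated unless the
#'   file extension is `.csv`; the first column holds probe ids, the header
#'   row holds sample ids.
#' @param annotation_path Path to the probe annotation table with columns
#'   `probe_id`, `entrez_id`, `symbol`. Empty fields mark missing annotation.
#' @param replicate_map_path Path to the replicate map with columns
#'   `sample_id`, `cell_type`.
#' @param species Species label stored on the atlas (`"mouse"`, `"human"` or
#'   `"synthetic"`).
#' @return An object of class `expression_atlas`: a list with components
#'   `values` (numeric matrix), `sample_cell_type` (named character vector,
#'   names are sample ids), `probe_annotation` (data frame with columns
#'   `probe_id`, `entrez_id`, `symbol`; `NA` where unannotated) and `species`.
#' @seealso [average_replicates()], [assign_hecs()], [generate_atlas()]
#' @export
read_atlas <- function(matrix_path, annotation_path, replicate_map_path,
                       species = "synthetic") {
  for (p in c(matrix_path, annotation_path, replicate_map_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  nf <- utils::count.fields(matrix_path, sep = sep, quote = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged expression matrix: row ", bad, " of ", matrix_path,
         " has ", nf[bad], " fields, expected ", nf[1L], call. = FALSE)
  }
  raw <- utils::read.table(matrix_path, sep = sep, header = TRUE,
                           row.names = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(raw)
  if (!is.numeric(values)) {
    bad <- which(!apply(raw, 1L, function(r) all(!is.na(suppressWarnings(as.numeric(r))))))[1L]
    stop("non-numeric expression values; first bad row: ",
         rownames(raw)[bad], call. = FALSE)
  }

  ann <- utils::read.table(annotation_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character", fill = TRUE)
  names(ann) <- tolower(names(ann))
  req <- c("probe_id", "entrez_id", "symbol")
  if (!all(req %in% names(ann))) {
    stop("annotation must have columns probe_id, entrez_id, symbol",
         call. = FALSE)
  }
  ann <- ann[, req]
  ann$entrez_id[!nzchar(ann$entrez_id)] <- NA_character_
  ann$symbol[!nzchar(ann$symbol)] <- NA_character_

  rep_map <- utils::read.table(replicate_map_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE, quote = "",
                               colClasses = "character")
  names(rep_map) <- tolower(names(rep_map))
  if (!all(c("sample_id", "cell_type") %in% names(rep_map))) {
    stop("replicate map must have columns sample_id, cell_type", call. = FALSE)
  }
  sample_cell_type <- stats::setNames(rep_map$cell_type, rep_map$sample_id)

  expression_atlas(values, sample_cell_type, ann, species)
}

#' Construct and validate an expression atlas in memory
#'
#' @param values Non-negative numeric matrix, probes x samples, with row and
#'   column names.
#' @param sample_cell_type Named character vector mapping sample id to cell
#'   type; must cover every column of `values`.
#' @param probe_annotation Data frame with columns `probe_id`, `entrez_id`,
#'   `symbol` (`NA` allowed in the last two). Probes absent from the table are
#'   treated as unannotated.
#' @param species Species label.
#' @return A validated `expression_atlas` object.
#' @export
expression_atlas <- function(values, sample_cell_type, probe_annotation,
                             species = "synthetic") {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs probe row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate probe ids in expression matrix", call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("expression values must be finite and non-negative; first offender ",
         "probe ", rownames(values)[bad[1L, 1L]], ", sample ",
         colnames(values)[bad[1L, 2L]], call. = FALSE)
  }
  missing_samples <- setdiff(colnames(values), names(sample_cell_type))
  if (length(missing_samples) > 0L) {
    stop("samples missing from replicate map: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  sample_cell_type <- sample_cell_type[colnames(values)]

  # align annotation to the matrix probes; unmatched probes stay unannotated
  idx <- match(rownames(values), probe_annotation$probe_id)
  ann <- data.frame(probe_id = rownames(values),
                    entrez_id = probe_annotation$entrez_id[idx],
                    symbol = probe_annotation$symbol[idx],
                    stringsAsFactors = FALSE)
  structure(list(values = values,
                 sample_cell_type = sample_cell_type,
                 probe_annotation = ann,
                 species = species),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat("Expression atlas (", x$species, "): ",
      nrow(x$values), " probes x ", ncol(x$values), " samples, ",
      length(unique(x$sample_cell_type)), " cell types; ",
      sum(!is.na(x$probe_annotation$entrez_id)), " annotated probes\n",
      sep = "")
  invisible(x)
}

#' Write an expression atlas to the three-file on-disk layout
#'
#' Emits `<prefix>_matrix.tsv`, `<prefix>_annotation.tsv` and
#' `<prefix>_replicates.tsv` under `dir`, in the exact dialects
#' [read_atlas()] consumes.
#'
#' @param atlas An `expression_atlas`.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix, default `"atlas"`.
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_atlas <- function(atlas, dir, prefix = "atlas") {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
             annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
             replicates = file.path(dir, paste0(prefix, "_replicates.tsv")))
  m <- data.frame(probe_id = rownames(atlas$values), atlas$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(m, paths[["matrix"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- atlas$probe_annotation
  ann$entrez_id[is.na(ann$entrez_id)] <- ""
  ann$symbol[is.na(ann$symbol)] <- ""
  utils::write.table(ann, paths[["annotation"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rep_map <- data.frame(sample_id = names(atlas$sample_cell_type),
                        cell_type = unname(atlas$sample_cell_type),
                        stringsAsFactors = FALSE)
  utils::write.table(rep_map, paths[["replicates"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Create a gene list
#'
#' Identifiers are normalized on construction: symbols are upper-cased (symbol
#' case is unstable across annotation sources), Entrez ids must be all-digit
#' strings. Duplicates after normalization are dropped, keeping the first
#' occurrence; the pre-deduplication count is retained for mapping reports.
#'
#' @param name List label.
#' @param ids Character vector of identifiers.
#' @param id_type `"symbol"` or `"entrez"`; declared, never inferred.
#' @return An object of class `gene_list` with fields `name`, `ids`,
#'   `id_type` and attribute `n_input`.
#' @export
gene_list <- function(name, ids, id_type = c("symbol", "entrez")) {
  id_type <- match.arg(id_type)
  ids <- as.character(ids)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) stop("gene list '", name, "' is empty", call. = FALSE)
  n_input <- length(ids)
  if (id_type == "symbol") {
    ids <- toupper(ids)
  } else {
    bad <- ids[!grepl("^[0-9]+$", ids)]
    if (length(bad) > 0L) {
      stop("parse error in list '", name, "': id_type is 'entrez' but found ",
           "non-digit token(s): ", paste(utils::head(bad, 3L), collapse = ", "),
           "; check that the proper identifier type is selected",
           call. = FALSE)
    }
  }
  ids <- ids[!duplicated(ids)]
  structure(list(name = name, ids = ids, id_type = id_type),
            n_input = n_input, class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat("Gene list '", x$name, "': ", length(x$ids), " unique ", x$id_type,
      " ids\n", sep = "")
  invisible(x)
}

#' Parse gene lists from text in single-, long- or wide-list dialects
#'
#' `single`: one identifier per line, yielding one list named `"list1"`.
#' `long`: two delimited columns `(list_name, id)`, grouped by name in order
#' of first appearance. `wide`: one column per list with list names in the
#' header row; columns of unequal length leave blank cells, which are skipped.
#'
#' @param text Character scalar holding the raw text (may contain newlines),
#'   or a character vector of lines.
#' @param id_type `"symbol"` or `"entrez"`.
#' @param dialect `"single"`, `"long"` or `"wide"`.
#' @param sep Field separator for the long and wide dialects (default tab).
#' @return A list of [gene_list()] objects.
#' @export
parse_gene_lists <- function(text, id_type = c("symbol", "entrez"),
                             dialect = c("single", "long", "wide"),
                             sep = "\t") {
  id_type <- match.arg(id_type)
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\r?\n")[[1]]
  } else {
    as.character(text)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no gene list content to parse", call. = FALSE)

  if (dialect == "single") {
    return(list(gene_list("list1", lines, id_type)))
  }

  fields <- strsplit(lines, sep, fixed = TRUE)
  if (dialect == "long") {
    ok <- vapply(fields, length, 1L) >= 2L
    if (!all(ok)) {
      stop("long dialect expects two fields per line; first bad line: ",
           which(!ok)[1L], call. = FALSE)
    }
    nm <- vapply(fields, `[`, "", 1L)
    id <- vapply(fields, `[`, "", 2L)
    lapply(unique(nm), function(l) gene_list(l, id[nm == l], id_type))
  } else {
    header <- trimws(fields[[1L]])
    if (length(fields) < 2L) stop("wide dialect has a header but no data rows",
                                  call. = FALSE)
    body <- fields[-1L]
    lapply(seq_along(header), function(j) {
      col <- vapply(body, function(f) if (length(f) >= j) f[j] else "", "")
      gene_list(header[j], col[nzchar(trimws(col))], id_type)
    })
  }
}

#' Read gene lists from a file
#'
#' @param path File path.
#' @inheritParams parse_gene_lists
#' @return A list of [gene_list()] objects.
#' @export
read_gene_lists <- function(path, id_type = c("symbol", "entrez"),
                            dialect = c("single", "long", "wide"),
                            sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parse_gene_lists(readLines(path, warn = FALSE), id_type, dialect, sep)
}

#' Count how many identifiers of each list map into a database universe
#'
#' For every list, reports the raw input count, the unique count after
#' normalization and the number of unique ids found in the database gene
#' universe. Lists with no mapped genes are flagged
#' `"No genes found in the database"` and should be excluded from enrichment;
#' flagging (rather than erroring) lets multi-list sessions continue.
#'
#' @param lists A [gene_list()] or list of them.
#' @param db A [hecs_db] database.
#' @return A data frame with columns `list_name`, `n_input`, `n_unique`,
#'   `n_mapped`, `flagged` (logical) and `note`.
#' @export
mapping_report <- function(lists, db) {
  if (inherits(lists, "gene_list")) lists <- list(lists)
  stopifnot(inherits(db, "hecs_db"))
  rows <- lapply(lists, function(gl) {
    mapped <- map_list_to_universe(gl, db)
    data.frame(list_name = gl$name,
               n_input = attr(gl, "n_input"),
               n_unique = length(gl$ids),
               n_mapped = length(mapped),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$n_mapped == 0L
  out$note <- ifelse(out$flagged, "No genes found in the database", "ok")
  out
}

# Translate a gene list into Entrez ids restricted to the database universe.
# Symbol lists go through the database's symbol table; Entrez lists intersect
# the universe directly.
map_list_to_universe <- function(gl, db) {
  if (gl$id_type == "entrez") {
    return(gl$ids[gl$ids %in% db$universe])
  }
  hit <- db$symbol_to_entrez[gl$ids]
  unique(hit[!is.na(hit)])
}

#' Write a HECS database to a TSV file
#'
#' The format is a comment header block (`# key: value` lines recording
#' species, threshold, universe size and the full cell-type registry) followed
#' by a three-column TSV body `(cell_type, entrez_id, symbol)`. Universe genes
#' that belong to no signature are carried as rows with an empty `cell_type`
#' field so that reading back a written database reproduces it exactly,
#' including empty signatures.
#'
#' @param db A [hecs_db] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_hecs_db()]
#' @export
write_hecs_db <- function(db, path) {
  stopifnot(inherits(db, "hecs_db"))
  header <- c(
    paste0("# species: ", db$species),
    paste0("# threshold: ", format(db$threshold, digits = 15)),
    paste0("# universe_size: ", length(db$universe)),
    paste0("# cell_types: ", paste(names(db$signatures), collapse = "|"))
  )
  sig_rows <- do.call(rbind, c(list(
    data.frame(cell_type = character(), entrez_id = character(),
               symbol = character(), stringsAsFactors = FALSE)),
    lapply(names(db$signatures), function(ct) {
      g <- db$signatures[[ct]]
      if (length(g) == 0L) return(NULL)
      data.frame(cell_type = ct, entrez_id = g,
                 symbol = unname(db$entrez_to_symbol[g]),
                 stringsAsFactors = FALSE)
    })))
  loose <- setdiff(db$universe, unique(sig_rows$entrez_id))
  if (length(loose) > 0L) {
    sig_rows <- rbind(sig_rows,
                      data.frame(cell_type = "", entrez_id = loose,
                                 symbol = unname(db$entrez_to_symbol[loose]),
                                 stringsAsFactors = FALSE))
  }
  sig_rows$symbol[is.na(sig_rows$symbol)] <- ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste("cell_type", "entrez_id", "symbol", sep = "\t"), con)
  if (nrow(sig_rows) > 0L) {
    writeLines(paste(sig_rows$cell_type, sig_rows$entrez_id, sig_rows$symbol,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a HECS database written by [write_hecs_db()]
#'
#' @param path File path.
#' @return A [hecs_db] object.
#' @export
read_hecs_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0L) {
      stop("HECS database file is missing required header field '", key, "'",
           call. = FALSE)
    }
    trimws(sub(paste0("^# ", key, ":"), "", m[1L]))
  }
  species <- get_field("species")
  threshold <- as.numeric(get_field("threshold"))
  cell_types <- strsplit(get_field("cell_types"), "|", fixed = TRUE)[[1L]]
  get_field("universe_size")  # presence required by the format

  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 1L) stop("HECS database file has no table", call. = FALSE)
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE, fill = TRUE)
  tab$symbol[is.na(tab$symbol)] <- ""
  signatures <- stats::setNames(
    lapply(cell_types, function(ct) tab$entrez_id[tab$cell_type == ct]),
    cell_types)
  universe <- sort(unique(tab$entrez_id))
  sym <- tab$symbol
  sym[!nzchar(sym)] <- NA_character_
  entrez_to_symbol <- stats::setNames(sym, tab$entrez_id)
  entrez_to_symbol <- entrez_to_symbol[!duplicated(names(entrez_to_symbol))]
  new_hecs_db(species, threshold, signatures, universe, entrez_to_symbol)
}

#' Write a table as TSV with a provenance comment header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param header Character vector of header lines; each is prefixed `"# "`.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(x, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0L) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
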