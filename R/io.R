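#' Read a paired expression matrix with its sample annotation
#'
#' The matrix file is TSV with a header row of sample ids and gene symbols
#' in the first column. The annotation file is TSV with columns
#' `sample_id`, `condition` (`tumor`/`normal`) and `pair_id`. Duplicate
#' gene rows are collapsed to the row with the highest mean intensity.
#'
#' @param matrix_path path to the expression TSV.
#' @param annotation_path path to the sample-annotation TSV.
#' @return an [expression_matrix].
#' @export
read_expression <- function(matrix_path, annotation_path) {
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character",
                    quote = "", comment.char = "")
  if (ncol(raw) < 2) {
    abort_riskmod("expression file needs a gene column plus samples",
                  "riskmod_parse_error")
  }
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(trimws(vals) %in% c("NA", "NaN", "")), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_riskmod(sprintf("non-numeric expression value '%s' at gene %s, sample %s",
                          vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                          colnames(vals)[bad[1, 2]]),
                  "riskmod_parse_error")
  }
  if (any(is.na(num))) {
    abort_riskmod("missing expression values are not supported",
                  "riskmod_parse_error")
  }
  rownames(num) <- genes
  num <- collapse_duplicate_genes(num)
  ann <- read.delim(annotation_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  expression_matrix(num, ann)
}

# keep, per duplicated gene id, the row with the highest mean intensity
collapse_duplicate_genes <- function(values) {
  if (!anyDuplicated(rownames(values))) {
    return(values)
  }
  means <- rowMeans(values)
  ord <- order(rownames(values), -means)
  values <- values[ord, , drop = FALSE]
  values[!duplicated(rownames(values)), , drop = FALSE]
}

#' Read an undirected edge list
#'
#' @param path 2-column TSV of gene-symbol pairs, no header. Lines with a
#'   different column count raise a parse error naming the line.
#' @param seeds optional seed genes used to flag nodes.
#' @return an [interaction_network].
#' @export
read_network <- function(path, seeds = character()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    abort_riskmod(sprintf("edge list line %d has %d fields (expected 2)",
                          which(nf != 2)[1], nf[nf != 2][1]),
                  "riskmod_parse_error")
  }
  m <- do.call(rbind, parts)
  interaction_network(data.frame(from = m[, 1], to = m[, 2],
                                 stringsAsFactors = FALSE),
                      seeds = seeds)
}

#' Write an edge list
#' @param network an [interaction_network].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  writeLines(paste(network$edges$from, network$edges$to, sep = "\t"), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: tab-separated lines of set name, description, then
#'   member genes.
#' @return named list mapping set name to character vector of genes.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort_riskmod(sprintf("GMT line %d has fewer than 3 fields", short[1]),
                  "riskmod_parse_error")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) {
    abort_riskmod("duplicate set names in GMT file", "riskmod_parse_error")
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of gene vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- rep("na", length(sets))
  }
  lines <- mapply(function(name, desc, genes) {
    paste(c(name, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Invert gene sets to a per-gene annotation map
#' @param sets named list set -> genes (as from [read_gene_sets]).
#' @param genes optional gene universe; genes without annotations get an
#'   empty set.
#' @return named list gene -> character vector of set names.
#' @export
annotation_map_from_sets <- function(sets, genes = NULL) {
  pairs_gene <- unlist(sets, use.names = FALSE)
  pairs_set <- rep(names(sets), lengths(sets))
  ann <- split(pairs_set, pairs_gene)
  ann <- lapply(ann, unique)
  if (!is.null(genes)) {
    out <- setNames(vector("list", length(genes)), genes)
    out[] <- list(character(0))
    out[intersect(genes, names(ann))] <- ann[intersect(genes, names(ann))]
    ann <- out
  }
  ann
}

#' Invert a per-gene annotation map to gene sets
#' @param annotations named list gene -> set names.
#' @return named list set -> genes.
#' @export
sets_from_annotation_map <- function(annotations) {
  keep <- lengths(annotations) > 0
  pairs_set <- unlist(annotations[keep], use.names = FALSE)
  pairs_gene <- rep(names(annotations)[keep], lengths(annotations[keep]))
  lapply(split(pairs_gene, pairs_set), unique)
}

MODULE_SCHEMA <- "riskmod-module-v1"

module_to_list <- function(module) {
  list(label = module$label,
       genes = as.list(module$genes),
       seed_genes = as.list(module$seed_genes),
       edges = unname(mapply(function(a, b) list(a, b),
                             module$edges$from, module$edges$to,
                             SIMPLIFY = FALSE)),
       scores = if (is.null(module$scores)) NULL else module$scores)
}

#' Write modules to a versioned JSON file
#'
#' Schema `riskmod-module-v1`: a top-level object with `schema` and a
#' `modules` array; each module records `label`, `genes`, `seed_genes`,
#' `edges` (pairs) and optional `scores`.
#'
#' @param modules list of [gene_module] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  payload <- list(schema = MODULE_SCHEMA,
                  modules = lapply(modules, module_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read modules from a `riskmod-module-v1` JSON file
#' @param path JSON path written by [write_modules].
#' @return list of [gene_module] objects.
#' @export
read_modules <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, MODULE_SCHEMA)) {
    abort_riskmod(sprintf("unsupported module schema '%s'",
                          as.character(payload$schema)),
                  "riskmod_parse_error")
  }
  lapply(payload$modules, function(m) {
    edges <- if (length(m$edges) == 0) {
      data.frame(from = character(0), to = character(0),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(from = vapply(m$edges, `[[`, character(1), 1),
                 to = vapply(m$edges, `[[`, character(1), 2),
                 stringsAsFactors = FALSE)
    }
    mod <- gene_module(unlist(m$genes), unlist(m$seed_genes), edges,
                       label = m$label)
    if (!is.null(m$scores)) {
      mod$scores <- m$scores
    }
    mod
  })
}
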