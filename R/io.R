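# File formats used by the pipeline. All outputs are plain text; every
# writer can stamp a header comment with the package version and seed so
# that runs are traceable.

output_header <- function(seed = NULL, config_hash = NULL) {
  v <- as.character(utils::packageVersion("consensusDR"))
  parts <- c(sprintf("consensusDR %s", v),
             if (!is.null(seed)) sprintf("seed=%s", seed),
             if (!is.null(config_hash)) sprintf("config=%s", config_hash))
  paste0("# ", paste(parts, collapse = " "))
}

write_with_header <- function(df, path, seed = NULL, config_hash = NULL, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config_hash), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_skip_header <- function(path, sep = ",", ...) {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write / read an expression matrix with its sample sheet
#'
#' The expression file is TSV with genes in rows (first column `gene`) and
#' a header row of sample ids; the sample sheet is TSV with columns
#' `sample_id` and `group` (`case`/`control`).
#'
#' @param ds An [expression_dataset()].
#' @param expr_path,sheet_path Output file paths.
#' @param seed Optional seed recorded in the header comment.
#' @return Invisibly, the expression path.
#' @export
write_expression <- function(ds, expr_path, sheet_path, seed = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene = ds$gene_ids, ds$matrix, check.names = FALSE)
  write_with_header(df, expr_path, seed = seed, sep = "\t")
  sheet <- data.frame(sample_id = colnames(ds$matrix), group = ds$groups)
  write_with_header(sheet, sheet_path, seed = seed, sep = "\t")
  invisible(expr_path)
}

#' @rdname write_expression
#' @param expr_path,sheet_path Paths written by [write_expression()].
#' @param stage,dataset_id Metadata for the reconstructed dataset.
#' @export
read_expression <- function(expr_path, sheet_path, stage = "MM", dataset_id = "DS1") {
  df <- read_skip_header(expr_path, sep = "\t")
  sheet <- read_skip_header(sheet_path, sep = "\t")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  groups <- sheet$group[match(colnames(m), sheet$sample_id)]
  expression_dataset(m, groups, stage = stage, dataset_id = dataset_id)
}

#' Write / read ranked repurposing-tool outputs
#'
#' Long CSV with columns `item_id`, `inhibition_score`, `tool_id`,
#' `dataset_id`, `stage`; rows ordered reverser-first within each
#' tool/dataset block.
#'
#' @param tool_outputs Nested list as from [gen_tool_outputs()].
#' @param path Output CSV path.
#' @param seed Optional seed for the header.
#' @return Invisibly, the path.
#' @export
write_tool_outputs <- function(tool_outputs, path, seed = NULL) {
  flat <- do.call(rbind, lapply(tool_outputs, function(ds) do.call(rbind, ds)))
  rownames(flat) <- NULL
  write_with_header(flat, path, seed = seed)
}

#' @rdname write_tool_outputs
#' @export
read_tool_outputs <- function(path) {
  flat <- read_skip_header(path)
  out <- list()
  for (ds in unique(flat$dataset_id)) {
    sub <- flat[flat$dataset_id == ds, , drop = FALSE]
    out[[ds]] <- lapply(split(sub, sub$tool_id), function(x) {
      x <- x[order(x$inhibition_score), , drop = FALSE]  # most negative first
      rownames(x) <- NULL
      x
    })
  }
  out
}

#' Write / read a GMT gene-set file
#'
#' Standard tab format: term id, description, then member genes. Reading
#' delegates to [fgsea::gmtPathways()].
#'
#' @param sets Named list of gene vectors, or a [gene_set_collection()].
#' @param path File path.
#' @return Invisibly the path (write); named list of gene vectors (read).
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write / read a fingerprint library as hex-encoded bit strings
#'
#' TSV with columns `drug_id` and `fingerprint` (hex, 4 bits per
#' character, zero-padded to the library's bit length).
#'
#' @param lib A [fp_library()].
#' @param path File path.
#' @param seed Optional seed for the header.
#' @return Invisibly the path (write); an `fp_library` (read).
#' @export
write_fingerprints <- function(lib, path, seed = NULL) {
  stopifnot(inherits(lib, "fp_library"))
  hex <- apply(lib$bits, 1, bits_to_hex)
  df <- data.frame(drug_id = lib$ids, fingerprint = hex, n_bits = lib$n_bits,
                   origin = lib$origin)
  write_with_header(df, path, seed = seed, sep = "\t")
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- read_skip_header(path, sep = "\t")
  n_bits <- df$n_bits[1]
  bits <- t(vapply(df$fingerprint, hex_to_bits, logical(n_bits), n_bits = n_bits))
  rownames(bits) <- df$drug_id
  fp_library(bits, origin = df$origin[1])
}

bits_to_hex <- function(bits) {
  bits <- as.logical(bits)
  pad <- (4 - length(bits) %% 4) %% 4
  bits <- c(bits, rep(FALSE, pad))
  nib <- matrix(bits, nrow = 4)
  vals <- as.integer(2^(3:0) %*% nib)
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
}

hex_to_bits <- function(hex, n_bits) {
  vals <- strtoi(strsplit(tolower(hex), "")[[1]], base = 16L)
  bits <- unlist(lapply(vals, function(v) bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L))
  bits[seq_len(n_bits)]
}

#' Write / read dose-response surfaces in long format
#'
#' DrugComb-style long CSV with columns `block_id`, `drug_row`,
#' `drug_col`, `conc_r`, `conc_c`, `response`.
#'
#' @param surfaces Named list of [dose_response_surface()] objects
#'   (names become block ids), or a single surface.
#' @param path File path.
#' @param seed Optional seed for the header.
#' @return Invisibly the path (write); named list of surfaces (read).
#' @export
write_dose_response <- function(surfaces, path, seed = NULL) {
  if (inherits(surfaces, "dr_surface")) surfaces <- list(block1 = surfaces)
  rows <- lapply(names(surfaces), function(b) {
    s <- surfaces[[b]]
    grid <- expand.grid(i = seq_along(s$conc_r), j = seq_along(s$conc_c))
    data.frame(block_id = b, drug_row = s$drug_row, drug_col = s$drug_col,
               conc_r = s$conc_r[grid$i], conc_c = s$conc_c[grid$j],
               response = s$response[cbind(grid$i, grid$j)])
  })
  write_with_header(do.call(rbind, rows), path, seed = seed)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  df <- read_skip_header(path)
  out <- lapply(split(df, df$block_id), function(b) {
    conc_r <- sort(unique(b$conc_r))
    conc_c <- sort(unique(b$conc_c))
    m <- matrix(NA_real_, length(conc_r), length(conc_c))
    m[cbind(match(b$conc_r, conc_r), match(b$conc_c, conc_c))] <- b$response
    if (anyNA(m)) stop("incomplete dose grid in block ", b$block_id[1])
    dose_response_surface(m, conc_r, conc_c,
                          drug_row = b$drug_row[1], drug_col = b$drug_col[1],
                          clip = FALSE)
  })
  out
}

#' Read a .smi SMILES file
#'
#' Whitespace-delimited lines: `SMILES id`. Lines without an id get one
#' generated from their position.
#'
#' @param path File path.
#' @return Named character vector of SMILES.
#' @export
read_smi <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  smiles <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("mol%03d", i)
  }, character(1))
  stats::setNames(smiles, ids)
}

#' Write a machine-readable truth sidecar
#'
#' Every synthetic artifact can be accompanied by a `.truth.json` sidecar
#' (same file stem) holding its planted ground truth, so recovery can be
#' scored without re-reading generator parameters.
#'
#' @param truth Any planted-truth object or list.
#' @param artifact_path Path of the generated artifact; the sidecar is
#'   written next to it.
#' @return Invisibly, the sidecar path.
#' @export
write_truth_sidecar <- function(truth, artifact_path) {
  sidecar <- paste0(tools::file_path_sans_ext(artifact_path), ".truth.json")
  payload <- unclass(truth)
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' @rdname write_truth_sidecar
#' @param path Sidecar path (or the artifact path; `.truth.json` is
#'   substituted).
#' @export
read_truth_sidecar <- function(path) {
  if (!endsWith(path, ".truth.json"))
    path <- paste0(tools::file_path_sans_ext(path), ".truth.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
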