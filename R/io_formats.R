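# Readers/writers for the formats the pipeline touches: TSV expression and
# interaction tables, FASTA, GMT, SIF / GraphML networks, JSON ground truth,
# YAML simulation configs. All writers are deterministic (same input ->
# byte-identical file) and all pairs round-trip losslessly.

#' Read an expression matrix from TSV
#'
#' Tab-separated, UTF-8, '.'-decimal, no quoting: header row of stage
#' names, first column transcript ids, numeric body. Duplicate ids,
#' missing values (no imputation) and negative or non-numeric cells are
#' rejected with the offending row/column named.
#'
#' @param path File path.
#' @param expected_unit Unit tag to attach ("RPM", "TPM" or "FPKM").
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, expected_unit = c("RPM", "TPM", "FPKM")) {
  expected_unit <- match.arg(expected_unit)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = character(0))
  .stop_if(ncol(df) < 2L, "expected an id column plus >= 1 stage column")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  .stop_if(length(dup) > 0,
           "duplicate transcript ids: ", paste(dup, collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                 dimnames = list(ids, colnames(df)[-1L]))
  for (j in 2L:ncol(df)) {
    raw <- df[[j]]
    miss <- which(is.na(raw) | raw == "")
    .stop_if(length(miss) > 0,
             "missing value at row ", miss[1L], " (", ids[miss[1L]],
             "), column '", colnames(df)[j], "'")
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num))
    .stop_if(length(bad) > 0,
             "non-numeric value '", raw[bad[1L]], "' at row ", bad[1L],
             " (", ids[bad[1L]], "), column '", colnames(df)[j], "'")
    neg <- which(num < 0)
    .stop_if(length(neg) > 0,
             "negative value at row ", neg[1L], " (", ids[neg[1L]],
             "), column '", colnames(df)[j], "'")
    vals[, j - 1L] <- num
  }
  expression_matrix(vals, expected_unit)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: header of stage names, first column
#' `transcript_id`. Doubles are written with shortest round-trip
#' precision, so `read(write(x))` reproduces `x` exactly.
#'
#' @param x Numeric matrix with transcript rownames and stage colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  m <- .as_plain_matrix(x)
  df <- data.frame(transcript_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Accepts T or U in any case; sequences are normalized to the uppercase
#' RNA alphabet (T -> U). Ids are the first whitespace-delimited token of
#' each header.
#'
#' @param path File path.
#' @return Named character vector of sequences (empty for an empty file).
#' @export
read_fasta <- function(path) {
  if (file.exists(path) && file.size(path) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- chartr("T", "U", toupper(as.character(set)))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' U is kept on output (RNA convention).
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One term per line: term id, description, then member genes, all
#' tab-separated. Members are de-duplicated (set semantics). A line with
#' fewer than three fields is malformed and reported with its line number.
#'
#' @param path File path.
#' @return Named list term -> character vector of member genes, with the
#'   descriptions attached as attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- list()
    attr(out, "description") <- stats::setNames(character(0), character(0))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  .stop_if(length(bad) > 0,
           "malformed GMT line ", bad[1L], ": expected >= 3 tab-separated fields")
  sets <- lapply(fgsea::gmtPathways(path), unique)
  desc <- stats::setNames(vapply(fields, `[`, "", 2L),
                          vapply(fields, `[`, "", 1L))
  attr(sets, "description") <- desc[names(sets)]
  sets
}

#' Read an interaction table from TSV
#'
#' Requires columns `mirna_id`, `target_id`, `target_kind`; optional
#' `source` (default "loaded") and `n_sites` (default 1). Duplicate
#' (miRNA, target, kind) rows are merged with site counts summed.
#'
#' @param path File path.
#' @return An [interaction_table()].
#' @export
read_interactions_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L) return(interaction_table())
  need <- c("mirna_id", "target_id", "target_kind")
  absent <- setdiff(need, colnames(df))
  .stop_if(length(absent) > 0,
           "missing column(s): ", paste(absent, collapse = ", "))
  if (!"source" %in% colnames(df)) df$source <- "loaded"
  if (!"n_sites" %in% colnames(df)) df$n_sites <- "1"
  n_sites <- suppressWarnings(as.integer(df$n_sites))
  .stop_if(nrow(df) > 0 && anyNA(n_sites), "non-integer n_sites value")
  interaction_table(df$mirna_id, df$target_id, df$target_kind,
                    df$source, n_sites)
}

#' Write an interaction table to TSV
#' @param x An [interaction_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions_tsv <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path, progress = FALSE)
  invisible(path)
}

# edge list of a triplet set: circRNA -sponges-> miRNA, miRNA -targets-> mRNA
.triplet_edges <- function(triplets) {
  if (nrow(triplets) == 0L) {
    return(data.frame(source = character(0), relation = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  }
  e1 <- unique(data.frame(source = triplets$circ_id, relation = "sponges",
                          target = triplets$mirna_id, stringsAsFactors = FALSE))
  e2 <- unique(data.frame(source = triplets$mirna_id, relation = "targets",
                          target = triplets$mrna_id, stringsAsFactors = FALSE))
  e <- rbind(e1, e2)
  e <- e[order(e$source, e$relation, e$target), , drop = FALSE]
  rownames(e) <- NULL
  e
}

.triplet_nodes <- function(triplets) {
  if (nrow(triplets) == 0L) {
    return(data.frame(id = character(0), layer = character(0),
                      direction = character(0), group = character(0),
                      stringsAsFactors = FALSE))
  }
  dir_circ <- ifelse(triplets$scheme == "circ_down_mir_up_mrna_down",
                     "down", "up")
  dir_mir <- ifelse(dir_circ == "down", "up", "down")
  nodes <- rbind(
    data.frame(id = triplets$circ_id, layer = "circRNA",
               direction = dir_circ, group = triplets$group,
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mirna_id, layer = "miRNA",
               direction = dir_mir, group = triplets$group,
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mrna_id, layer = "mRNA",
               direction = dir_circ, group = triplets$group,
               stringsAsFactors = FALSE)
  )
  nodes <- unique(nodes)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

#' Export a ceRNA network for visualization
#'
#' SIF uses relationship tags `sponges` (circRNA -> miRNA) and `targets`
#' (miRNA -> mRNA); GraphML additionally carries node attributes `layer`,
#' `direction` and `group`. Nodes and edges are written in lexicographic
#' order so identical networks always produce byte-identical files. An
#' empty triplet list yields an empty network file.
#'
#' @param triplets data.frame from [build_triplets()].
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(triplets, path, format = c("sif", "graphml")) {
  .stop_if(length(format) == 1L && !format %in% c("sif", "graphml"),
           "unknown network format: ", format)
  format <- match.arg(format)
  edges <- .triplet_edges(triplets)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", edges$source, edges$relation, edges$target)
    writeLines(lines, path)
    return(invisible(path))
  }
  nodes <- .triplet_nodes(triplets)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$source, to = edges$target,
                   relation = edges$relation, stringsAsFactors = FALSE),
    directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a SIF network file
#' @param path File path.
#' @return data.frame with columns `source`, `relation`, `target`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(source = character(0), relation = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  .stop_if(length(bad) > 0, "malformed SIF line ", bad[1L])
  data.frame(
    source = vapply(fields, `[`, "", 1L),
    relation = vapply(fields, `[`, "", 2L),
    target = vapply(fields, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

#' Read a GraphML network file
#' @param path File path.
#' @return An igraph graph.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

.chr <- function(x) if (length(x) == 0L) character(0) else as.character(x)
.int <- function(x) if (length(x) == 0L) integer(0) else as.integer(x)

#' Write planted ground truth to JSON
#'
#' Serializes a [generate_dataset()] ground-truth record (planted
#' expressed-stage patterns, specificity labels, temporal pattern labels,
#' DE truth, planted triplets and seed sites) to a JSON document that
#' [read_ground_truth()] restores exactly.
#'
#' @param gt A `ground_truth` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  ser <- list(
    expressed = lapply(gt$expressed, function(m)
      list(ids = rownames(m), stages = colnames(m),
           values = unname(m))),
    specific_stage = lapply(gt$specific_stage, function(v)
      list(ids = names(v), stage = unname(v))),
    pattern_labels = list(ids = names(gt$pattern_labels),
                          label = unname(gt$pattern_labels)),
    de_truth = as.list(gt$de_truth),
    planted_triplets = as.list(gt$planted_triplets),
    planted_sites = as.list(gt$planted_sites)
  )
  jsonlite::write_json(ser, path, na = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read planted ground truth from JSON
#' @param path File written by [write_ground_truth()].
#' @return A `ground_truth` list.
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  expressed <- lapply(raw$expressed, function(e) {
    ids <- .chr(e$ids); stages <- .chr(e$stages)
    if (is.matrix(e$values)) {
      m <- matrix(as.logical(e$values), nrow = nrow(e$values))
    } else {
      m <- matrix(as.logical(unlist(e$values)), nrow = length(ids),
                  ncol = length(stages), byrow = TRUE)
    }
    dimnames(m) <- list(ids, stages)
    m
  })
  specific <- lapply(raw$specific_stage, function(s) {
    v <- .chr(unlist(lapply(s$stage, function(x) if (is.null(x)) NA_character_ else x)))
    if (length(s$ids) > 0 && length(v) == 0) v <- rep(NA_character_, length(s$ids))
    stats::setNames(v, .chr(s$ids))
  })
  df_from <- function(l, chr_cols, int_cols = character(0)) {
    cols <- c(lapply(stats::setNames(chr_cols, chr_cols),
                     function(cc) .chr(l[[cc]])),
              lapply(stats::setNames(int_cols, int_cols),
                     function(cc) .int(l[[cc]])))
    do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  }
  gt <- list(
    expressed = expressed,
    specific_stage = specific,
    pattern_labels = stats::setNames(.chr(raw$pattern_labels$label),
                                     .chr(raw$pattern_labels$ids)),
    de_truth = df_from(raw$de_truth,
                       c("layer", "transcript_id", "comparison", "direction")),
    planted_triplets = df_from(raw$planted_triplets,
                               c("circ_id", "mirna_id", "mrna_id",
                                 "comparison", "group", "scheme")),
    planted_sites = df_from(raw$planted_sites,
                            c("mirna_id", "target_id", "target_kind",
                              "site_type"), c("start", "end"))
  )
  class(gt) <- "ground_truth"
  gt
}

#' Read a simulation config from YAML
#'
#' Fields are passed to [simulation_config()], so defaults apply to
#' anything the file omits and the usual validation runs.
#'
#' @param path YAML file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  do.call(simulation_config, cfg)
}

#' Write a simulation config to YAML
#' @param config A `sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a synthetic tri-omics dataset to a directory
#'
#' One TSV per normalized matrix (`circ_rpm.tsv`, `mirna_tpm.tsv`,
#' `mrna_fpkm.tsv`), one per count matrix, per-stage library sizes,
#' mRNA effective lengths, sequences as FASTA (if present) and the ground
#' truth as JSON.
#'
#' @param dataset An `omics_dataset` from [generate_dataset()].
#' @param truth Matching `ground_truth` (optional).
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, truth = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_expression_tsv(dataset$circ, p("circ_rpm.tsv"))
  write_expression_tsv(dataset$mirna, p("mirna_tpm.tsv"))
  write_expression_tsv(dataset$mrna, p("mrna_fpkm.tsv"))
  write_expression_tsv(dataset$circ_counts, p("circ_counts.tsv"))
  write_expression_tsv(dataset$mirna_counts, p("mirna_counts.tsv"))
  write_expression_tsv(dataset$mrna_counts, p("mrna_counts.tsv"))
  readr::write_tsv(data.frame(stage = names(dataset$lib_sizes),
                              library_size = unname(dataset$lib_sizes)),
                   p("library_sizes.tsv"), progress = FALSE)
  readr::write_tsv(data.frame(transcript_id = names(dataset$mrna_lengths),
                              length_nt = unname(dataset$mrna_lengths)),
                   p("mrna_lengths.tsv"), progress = FALSE)
  if (!is.null(dataset$sequences) && length(dataset$sequences) > 0) {
    write_fasta(dataset$sequences, p("sequences.fa"))
  }
  if (!is.null(truth)) write_ground_truth(truth, p("ground_truth.json"))
  invisible(outdir)
}
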