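#' Read a drug-disease dataset from delimited text files
#'
#' The two similarity files are dense tab-separated matrices with a header
#' row of identifiers and identifiers in the first column. The association
#' file is either (a) the same dense layout (entries 0/1), or (b) an edge
#' list with two or three columns `drug_id<TAB>disease_id[<TAB>value]` and no
#' header; the format is auto-detected. Edge-list identifiers are resolved
#' against the similarity-file labels, and pairs absent from the edge list
#' are 0.
#'
#' @param assoc_path path to the association matrix or edge list.
#' @param drug_sim_path,disease_sim_path paths to the similarity matrices.
#' @return An [anmf_dataset].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(assoc_path, drug_sim_path, disease_sim_path) {
  for (p in c(assoc_path, drug_sim_path, disease_sim_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  drug_sim <- .read_dense_matrix(drug_sim_path)
  disease_sim <- .read_dense_matrix(disease_sim_path)
  drug_ids <- rownames(drug_sim)
  disease_ids <- rownames(disease_sim)

  R <- .read_assoc(assoc_path, drug_ids, disease_ids)
  anmf_dataset(R, drug_sim, disease_sim,
               drug_ids = drug_ids, disease_ids = disease_ids)
}

.read_dense_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path, call. = FALSE)
  m
}

# Dense if the first row parses as a header (corner cell is not a drug id,
# remaining fields are known disease ids); otherwise edge list.
.read_assoc <- function(path, drug_ids, disease_ids) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  dense <- length(first) > 1L && all(first[-1] %in% disease_ids) &&
    !(first[1] %in% drug_ids)
  if (dense) {
    M <- .read_dense_matrix(path)
    .check_ids(rownames(M), drug_ids, path, "drug")
    .check_ids(colnames(M), disease_ids, path, "disease")
    # allow a row/column subset order differing from the similarity files
    if (!identical(rownames(M), drug_ids) || !identical(colnames(M), disease_ids)) {
      if (!setequal(rownames(M), drug_ids) || !setequal(colnames(M), disease_ids)) {
        stop("association matrix in ", path,
             " does not cover the same identifiers as the similarity files",
             call. = FALSE)
      }
      M <- M[drug_ids, disease_ids, drop = FALSE]
    }
    return(M)
  }
  edges <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(edges) %in% 2:3) {
    stop("association file ", path,
         " is neither a labeled dense matrix nor a 2/3-column edge list",
         call. = FALSE)
  }
  .check_ids(unique(edges[[1]]), drug_ids, path, "drug")
  .check_ids(unique(edges[[2]]), disease_ids, path, "disease")
  if (ncol(edges) == 3L && !all(edges[[3]] %in% c(0, 1))) {
    stop("edge-list values must be 0/1 in ", path, call. = FALSE)
  }
  R <- matrix(0, length(drug_ids), length(disease_ids),
              dimnames = list(drug_ids, disease_ids))
  keep <- if (ncol(edges) == 3L) edges[[3]] == 1 else rep(TRUE, nrow(edges))
  R[cbind(match(edges[[1]][keep], drug_ids),
          match(edges[[2]][keep], disease_ids))] <- 1
  R
}

.check_ids <- function(found, known, path, what) {
  missing <- setdiff(found, known)
  if (length(missing)) {
    stop("unknown ", what, " identifier '", missing[1], "' in ", path,
         call. = FALSE)
  }
}

#' Write a dataset as tab-separated text files
#'
#' Writes `assoc.tsv`, `drug_sim.tsv` and `disease_sim.tsv` into `dir`.
#' Dense output round-trips bit-exactly through [read_dataset()] (17
#' significant digits).
#'
#' @param d an [anmf_dataset].
#' @param dir output directory (created if needed).
#' @param assoc_format `"dense"` (labeled 0/1 matrix) or `"edges"`
#'   (two-column edge list of the verified pairs).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(d, dir, assoc_format = c("dense", "edges")) {
  stopifnot(inherits(d, "anmf_dataset"))
  assoc_format <- match.arg(assoc_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (assoc_format == "dense") {
    .write_dense_matrix(d$R, file.path(dir, "assoc.tsv"))
  } else {
    idx <- which(d$R == 1, arr.ind = TRUE)
    edges <- data.frame(drug = d$drug_ids[idx[, 1]],
                        disease = d$disease_ids[idx[, 2]])
    write.table(edges, file.path(dir, "assoc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  .write_dense_matrix(d$drug_sim, file.path(dir, "drug_sim.tsv"))
  .write_dense_matrix(d$disease_sim, file.path(dir, "disease_sim.tsv"))
  invisible(dir)
}

.write_dense_matrix <- function(M, path) {
  # %.17g round-trips IEEE doubles exactly
  chr <- matrix(sprintf("%.17g", M), nrow(M), dimnames = dimnames(M))
  lines <- c(
    paste(c("id", colnames(M)), collapse = "\t"),
    paste(rownames(M), apply(chr, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
}
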