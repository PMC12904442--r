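#' Write a simulated cohort to a directory of delimited text files
#'
#' Writes `subjects.csv`, `labs.csv`, `genomics.csv`, `embeddings.csv`,
#' `pathways.csv`, `clinical.csv`, `cancer_specific.csv` and a
#' `manifest.json` sidecar recording the seed, generator version and table
#' schemas.
#'
#' @param cohort a `pancox_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  w(cohort$subjects, "subjects.csv")
  w(cohort$labs, "labs.csv")
  w(cohort$genomics, "genomics.csv")
  emb <- data.frame(gene_id = rownames(cohort$embeddings),
                    cohort$embeddings, check.names = FALSE)
  w(emb, "embeddings.csv")
  pw <- do.call(rbind, lapply(names(cohort$pathways), function(p)
    data.frame(pathway_id = p, gene_id = cohort$pathways[[p]])))
  w(pw, "pathways.csv")
  w(cohort$clinical, "clinical.csv")
  w(cohort$cancer_specific, "cancer_specific.csv")
  manifest <- list(
    generator = "pancox",
    version = as.character(utils::packageVersion("pancox")),
    seed = cohort$config$seed,
    n_subjects = nrow(cohort$subjects),
    truncation_fraction = cohort$truth$truncation_fraction,
    tables = c("subjects", "labs", "genomics", "embeddings", "pathways",
               "clinical", "cancer_specific"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' The generating truth is not persisted; the returned object supports the
#' feature/model pipeline but not truth-based oracles.
#'
#' @param dir directory path
#' @return a `pancox_cohort` (without `truth`)
#' @export
read_cohort <- function(dir) {
  r <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  emb_df <- r("embeddings.csv")
  emb <- as.matrix(emb_df[, -1, drop = FALSE])
  rownames(emb) <- emb_df$gene_id
  pw_df <- r("pathways.csv")
  pathways <- split(pw_df$gene_id, pw_df$pathway_id)
  out <- list(subjects = r("subjects.csv"), labs = r("labs.csv"),
              genomics = r("genomics.csv"), embeddings = emb,
              pathways = pathways, clinical = r("clinical.csv"),
              cancer_specific = r("cancer_specific.csv"),
              truth = NULL, config = NULL)
  class(out) <- "pancox_cohort"
  out
}

#' Read a simulation config from structured JSON
#'
#' Fields mirror the arguments of [sim_config()]; absent fields take the
#' package defaults. `gene_catalog` and `lab_catalog` may be given as
#' arrays of records.
#'
#' @param path JSON file path
#' @return a `sim_config`
#' @export
read_sim_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- j[intersect(names(j), names(formals(sim_config)))]
  if (!is.null(args$gene_catalog)) args$gene_catalog <- as.data.frame(args$gene_catalog)
  if (!is.null(args$lab_catalog)) args$lab_catalog <- as.data.frame(args$lab_catalog)
  if (!is.null(args$specific_beta) && !is.list(args$specific_beta))
    args$specific_beta <- as.list(as.data.frame(args$specific_beta))
  do.call(sim_config, args)
}
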