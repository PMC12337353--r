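#' Read a simulation configuration file
#'
#' Flat YAML key-value document whose keys mirror [sim_params()] argument
#' names exactly; unknown keys are errors. CLI-style overrides can be
#' supplied as a named list and take precedence.
#'
#' @param path YAML file.
#' @param overrides named list of overriding values.
#' @return a [sim_params()] object.
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg[names(overrides)] <- overrides
  allowed <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(sim_params, cfg)
}

#' Write a trajectory to a directory of delimited tables plus metadata
#'
#' Writes `trajectory.tsv` (long format: t, genotype_index, B, V),
#' `gene_abundance.tsv` (t, gene, nB_gene, nV_gene) and `run_meta.json`
#' (full parameters, seed, package version, termination reason, first-loss
#' times).
#'
#' @param traj a [run_simulation()] record.
#' @param dir output directory (created if missing).
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "trajectory_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  K <- ncol(traj$B); L <- ncol(traj$gene_B); nt <- length(traj$times)
  long <- data.frame(t = rep(traj$times, K),
                     genotype_index = rep(seq_len(K) - 1L, each = nt),
                     B = as.vector(traj$B), V = as.vector(traj$V))
  write.table(long, file.path(dir, "trajectory.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  genes <- data.frame(t = rep(traj$times, L),
                      gene = rep(seq_len(L) - 1L, each = nt),
                      nB_gene = as.vector(traj$gene_B),
                      nV_gene = as.vector(traj$gene_V))
  write.table(genes, file.path(dir, "gene_abundance.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  pt <- persistence_times(traj)
  meta <- list(params = unclass(traj$params),
               package_version = as.character(utils::packageVersion("panhgt")),
               termination = traj$termination, t_end = traj$t_end,
               steps_done = traj$steps_done,
               first_loss = pt[c("gene_B", "gene_V", "gene", "genotype_B",
                                 "genotype_V", "genotype")],
               zero_touch_total = traj$zero_touch_total)
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Read back a trajectory directory written by [write_trajectory()]
#'
#' Returns a lightweight list (not a full `trajectory_record`): the wide
#' B/V/gene matrices, times, and the metadata. Sufficient for the analysis
#' CLI subcommands.
#'
#' @param dir directory produced by [write_trajectory()].
#' @export
read_trajectory <- function(dir) {
  long <- read.table(file.path(dir, "trajectory.tsv"), header = TRUE,
                     sep = "\t")
  genes <- read.table(file.path(dir, "gene_abundance.tsv"), header = TRUE,
                      sep = "\t")
  meta <- jsonlite::read_json(file.path(dir, "run_meta.json"),
                              simplifyVector = TRUE)
  times <- unique(long$t)
  K <- length(unique(long$genotype_index))
  L <- length(unique(genes$gene))
  list(times = times,
       B = matrix(long$B, ncol = K), V = matrix(long$V, ncol = K),
       gene_B = matrix(genes$nB_gene, ncol = L),
       gene_V = matrix(genes$nV_gene, ncol = L),
       meta = meta)
}
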