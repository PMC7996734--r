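# End-to-end pipeline: k-best hishapes -> pairwise barriers -> Arrhenius
# rates -> master-equation trajectory, with TSV artifacts on disk.

#' Run configuration for the folding-kinetics pipeline
#'
#' Collects every tunable parameter of the three pipeline steps with its
#' default. Serializable to a plain-text `key = value` file.
#'
#' @param k Number of hishape classes.
#' @param level Abstraction level.
#' @param bp_threshold Base-pairing filter threshold.
#' @param x_filter Optional external-loop pseudo-energy filter.
#' @param lam,phi,normalization Covariance scoring (see [covariance_params()]).
#' @param energy_backend `"toy"` or `"turner"`.
#' @param width Beam width for barrier estimation.
#' @param temperature Kelvin.
#' @param prefactor Arrhenius prefactor (sets the time unit).
#' @param t_start,t_end,t_points Log-spaced output time grid.
#' @param neg_only Keep only classes with strictly negative pseudo energy
#'   (the open chain is then appended as an extra state).
#' @param start_open Start the simulation from the open chain instead of the
#'   rank-1 class.
#' @return A list of class `run_config`.
#' @export
run_config <- function(k = 10L, level = "h", bp_threshold = 0.5,
                       x_filter = NULL, lam = -1.0, phi = 1.0,
                       normalization = "per_M", energy_backend = "toy",
                       width = 16L, temperature = 310.15, prefactor = 1.0,
                       t_start = 1e-2, t_end = 1e10, t_points = 60L,
                       neg_only = FALSE, start_open = FALSE) {
  cfg <- list(k = as.integer(k), level = level, bp_threshold = bp_threshold,
              x_filter = x_filter, lam = lam, phi = phi,
              normalization = normalization, energy_backend = energy_backend,
              width = as.integer(width), temperature = temperature,
              prefactor = prefactor, t_start = t_start, t_end = t_end,
              t_points = as.integer(t_points), neg_only = neg_only,
              start_open = start_open)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration
#'
#' Plain-text `key = value` serialization; `NULL` fields are omitted.
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    if (is.null(v)) "" else paste0(nm, " = ", v)
  }, character(1))
  writeLines(lines[nzchar(lines)], path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[[:space:]]*=[[:space:]]*")
  defaults <- run_config()
  cfg <- defaults
  for (f in kv) {
    nm <- f[1]
    if (!nm %in% names(defaults)) stop("unknown config key: ", nm)
    template <- defaults[[nm]]
    cfg[[nm]] <- if (is.logical(template)) as.logical(f[2])
                 else if (nm %in% c("level", "normalization", "energy_backend")) f[2]
                 else as.numeric(f[2])
  }
  cfg$k <- as.integer(cfg$k); cfg$width <- as.integer(cfg$width)
  cfg$t_points <- as.integer(cfg$t_points)
  cfg
}

resolve_backend <- function(name) {
  switch(name, toy = toy_backend(), turner = turner_backend(),
         stop("unknown energy backend: ", name))
}

#' Run the consensus folding-kinetics pipeline
#'
#' Reads an alignment, computes the k best hishape classes, estimates
#' pairwise refolding barriers between their representatives (each pair may
#' route through the remaining hishreps as single intermediates), builds the
#' Arrhenius rate matrix and integrates the master equation. Writes
#' `hishapes.tsv`, `barriers.tsv`, `rates.tsv`, `trajectory.tsv` and
#' `config.txt` into `out_dir`. Output is deterministic: repeated runs with
#' the same configuration are byte-identical.
#'
#' @param aln_path Path to an aligned FASTA or Clustal file.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [run_config()].
#' @param format Alignment format.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `classes`, `barriers`, `rate_matrix`,
#'   `trajectory` and the output file paths.
#' @export
run_pipeline <- function(aln_path, out_dir, cfg = run_config(),
                         format = c("fasta", "clustal"), quiet = FALSE) {
  format <- match.arg(format)
  aln <- read_alignment(aln_path, format)
  res <- run_pipeline_aln(aln, cfg, quiet = quiet)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    hishapes = file.path(out_dir, "hishapes.tsv"),
    barriers = file.path(out_dir, "barriers.tsv"),
    rates = file.path(out_dir, "rates.tsv"),
    trajectory = file.path(out_dir, "trajectory.tsv"),
    config = file.path(out_dir, "config.txt"))
  tab <- res$classes
  tab$energy <- sprintf("%.2f", tab$energy)
  tab$mean_energy <- sprintf("%.2f", tab$mean_energy)
  tab$covariance_term <- sprintf("%.2f", tab$covariance_term)
  utils::write.table(tab, paths$hishapes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(state_a = rep(rownames(res$barriers),
                             times = ncol(res$barriers)),
               state_b = rep(colnames(res$barriers),
                             each = nrow(res$barriers)),
               barrier = sprintf("%.2f", as.vector(res$barriers))),
    paths$barriers, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    cbind(state = res$rate_matrix$states,
          as.data.frame(format(res$rate_matrix$R, digits = 8))),
    paths$rates, sep = "\t", quote = FALSE, row.names = FALSE)
  write_trajectory(res$trajectory, paths$trajectory)
  write_run_config(cfg, paths$config)
  invisible(c(res, list(paths = paths)))
}

#' @rdname run_pipeline
#' @param aln An [rna_alignment()] (in-memory variant).
#' @export
run_pipeline_aln <- function(aln, cfg = run_config(), quiet = FALSE) {
  backend <- resolve_backend(cfg$energy_backend)
  params <- covariance_params(cfg$lam, cfg$phi, cfg$normalization)
  fs_cfg <- folding_space_config(k = cfg$k, level = cfg$level,
                                 bp_threshold = cfg$bp_threshold,
                                 x_filter = cfg$x_filter)
  classes <- kbest_hishapes(aln, fs_cfg, backend, params)
  if (!nrow(classes)) stop("empty folding space (no classes)")
  structs <- attr(classes, "structures")
  class(classes) <- "data.frame"
  attr(classes, "structures") <- NULL
  if (cfg$neg_only) {
    keep <- classes$energy < 0 | classes$hishape == "[_]"
    if (!any(keep)) stop("no strictly negative hishape classes")
    structs <- structs[keep]
    classes <- classes[keep, , drop = FALSE]
    classes$rank <- seq_len(nrow(classes))
  }
  if ((cfg$neg_only || cfg$start_open) && !any(classes$hishape == "[_]")) {
    open <- rna_structure(aln$L)
    e <- consensus_pseudo_energy(aln, open, backend, params)
    classes <- rbind(classes,
                     data.frame(rank = nrow(classes) + 1L, hishape = "[_]",
                                energy = e$total, mean_energy = e$mean_energy,
                                covariance_term = e$covariance_term,
                                hishrep = write_dotbracket(open)))
    structs <- c(structs, list(open))
  }
  n <- nrow(classes)
  if (!quiet) message(n, " state(s): ", paste(classes$hishape, collapse = " "))
  barriers <- matrix(NA_real_, n, n,
                     dimnames = list(classes$hishape, classes$hishape))
  diag(barriers) <- classes$energy
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        path <- indirect_barrier(aln, structs[[a]], structs[[b]],
                                 intermediates = structs[-c(a, b)],
                                 width = cfg$width, backend = backend,
                                 params = params)
        barriers[a, b] <- barriers[b, a] <- path$barrier
      }
    }
  }
  energies <- stats::setNames(classes$energy, classes$hishape)
  rm <- build_rate_matrix(energies, barriers, cfg$temperature, cfg$prefactor)
  p0 <- stats::setNames(rep(0, n), classes$hishape)
  start <- if (cfg$start_open && any(classes$hishape == "[_]")) "[_]"
           else classes$hishape[1]
  p0[start] <- 1
  times <- kinetics_times(cfg$t_start, cfg$t_end, cfg$t_points)
  traj <- simulate_kinetics(rm, p0, times)
  list(classes = classes, barriers = barriers, rate_matrix = rm,
       trajectory = traj, start = start)
}
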