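#' Read a flat key = value run configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and
#' `#` comments ignored. Values holding comma-separated integers are
#' split into integer vectors.
#'
#' @param path Config file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3]
  if (length(bad) > 0)
    stop("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  out <- lapply(vals, function(v) {
    if (grepl("^[0-9]+(\\s*,\\s*[0-9]+)*$", v))
      as.integer(strsplit(v, "\\s*,\\s*")[[1]])
    else if (grepl("^-?[0-9.]+$", v)) as.numeric(v)
    else v
  })
  setNames(out, keys)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full family-analysis pipeline
#'
#' Orchestrates the whole workflow: sequences are aligned pairwise into
#' an identity / conserved-count matrix, clustered into a UPGMA
#' cladogram, multiply aligned, mapped onto the reference numbering,
#' reduced to a residue table at the requested positions, and the table
#' is profiled (variability, entropy, hydropathy range,
#' conserved/variable/selective classification) and scored for cleft
#' hydrophobicity. In *fixture mode* — `residue_table` given instead of
#' `fasta` — the alignment stages are skipped and the pocket analysis
#' runs directly on the table, which reproduces a published active-site
#' table analysis without any sequence input.
#'
#' Configuration fields (a named list, or a file parsed by
#' [read_run_config()]): `fasta` (path) or `residue_table` (path or
#' bundled fixture name, see [isopocket_fixture()]); `reference`
#' (reference isoform label; required with `fasta`); `positions`
#' (integer vector, or path to a one-integer-per-line file; required
#' with `fasta`); `scale` (hydropathy scale TSV; default the built-in
#' Kyte-Doolittle scale); `entropy_threshold` (default 1.0 bit);
#' `contacts` — integer vector (explicit contact set), `"none"` (empty
#' set), or a PDB path (structure-derived via [ligand_contacts()]);
#' `pdb` (optional PDB paths superposed onto the first for an RMSD
#' summary); `outdir` (required); `seed` (recorded in the manifest).
#'
#' Outputs written to `outdir`: `identity_matrix.tsv`, `cladogram.nwk`,
#' `msa.fasta`, `residue_table.tsv` (sequence mode only),
#' `position_profiles.tsv`, `pocket_scores.tsv`,
#' `superpositions.tsv` (with `pdb`), and `manifest.json`. Any stage
#' failure aborts with the stage named and removes partial outputs.
#'
#' @param config Named list or path to a key = value config file.
#' @return Invisibly, a list with the computed objects (`identity`,
#'   `tree`, `msa`, `table`, `profiles`, `scores`, `contacts`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  stopifnot(is.list(config))
  if (is.null(config$outdir)) stop("config field 'outdir' is required")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(fn, writer) {
    path <- file.path(outdir, fn)
    writer(path)
    written <<- c(written, path)
    path
  }
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  threshold <- if (is.null(config$entropy_threshold)) 1.0
               else config$entropy_threshold
  scale <- if (is.null(config$scale)) kd_scale()
           else pipeline_stage("scale", read_hydropathy_scale(config$scale))

  tryCatch({
    res <- list()
    if (!is.null(config$fasta)) {
      if (is.null(config$reference))
        stop("config field 'reference' is required with 'fasta'")
      if (is.null(config$positions))
        stop("config field 'positions' is required with 'fasta'")
      positions <- config$positions
      if (is.character(positions))
        positions <- pipeline_stage("positions",
          as.integer(readLines(positions, warn = FALSE)))
      family <- pipeline_stage("read_fasta", read_fasta(config$fasta))
      res$identity <- pipeline_stage("identity_matrix",
                                     identity_matrix(family))
      emit("identity_matrix.tsv",
           function(p) write_identity_matrix(res$identity, p))
      res$tree <- pipeline_stage("cladogram",
                                 upgma(identity_to_distance(res$identity)))
      emit("cladogram.nwk", function(p) write_newick(res$tree, p))
      res$msa <- pipeline_stage("progressive_msa", progressive_msa(family))
      emit("msa.fasta", function(p) write_msa(res$msa, p))
      map <- pipeline_stage("reference_map",
                            build_reference_map(res$msa, config$reference))
      res$table <- pipeline_stage("residue_table",
                                  extract_residue_table(map, positions))
      emit("residue_table.tsv",
           function(p) write_residue_table(res$table, p))
    } else if (!is.null(config$residue_table)) {
      path <- config$residue_table
      if (!file.exists(path))
        path <- pipeline_stage("residue_table", isopocket_fixture(path))
      res$table <- pipeline_stage("residue_table", read_residue_table(path))
    } else {
      stop("config must name either 'fasta' or 'residue_table'")
    }

    contacts <- config$contacts
    if (is.null(contacts)) contacts <- c(67L, 91L, 131L)
    if (is.character(contacts)) {
      if (identical(contacts, "none")) {
        contacts <- integer(0)
      } else {
        s <- pipeline_stage("contacts", read_pdb(contacts))
        contacts <- pipeline_stage("contacts", ligand_contacts(s))
      }
    }
    res$contacts <- as.integer(contacts)

    res$profiles <- pipeline_stage("profiles", {
      prof <- position_profiles(res$table, scale)
      classify_positions(prof, threshold, res$contacts)
    })
    emit("position_profiles.tsv", function(p)
      write.table(res$profiles, p, sep = "\t", quote = FALSE,
                  row.names = FALSE))
    res$scores <- pipeline_stage("scores", score_report(res$table, scale))
    emit("pocket_scores.tsv", function(p)
      write.table(res$scores, p, sep = "\t", quote = FALSE,
                  row.names = FALSE))

    if (!is.null(config$pdb) && length(config$pdb) > 1) {
      res$superpositions <- pipeline_stage("superpose", {
        structs <- lapply(config$pdb, read_pdb)
        ref <- structs[[1]]
        do.call(rbind, lapply(structs[-1], function(s) {
          sp <- superpose_sites(s, ref)
          data.frame(moving = s$label, fixed = ref$label,
                     rmsd = sp$rmsd, n_atoms = sp$n)
        }))
      })
      emit("superpositions.tsv", function(p)
        write.table(res$superpositions, p, sep = "\t", quote = FALSE,
                    row.names = FALSE))
    }

    res$manifest <- list(
      package = "isopocket",
      version = as.character(utils::packageVersion("isopocket")),
      inputs = config[intersect(names(config),
                                c("fasta", "residue_table", "reference",
                                  "positions", "scale", "pdb"))],
      parameters = list(entropy_threshold = threshold,
                        contacts = res$contacts),
      seed = config$seed,
      outputs = basename(written))
    manifest_path <- file.path(outdir, "manifest.json")
    jsonlite::write_json(res$manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
    written <- c(written, manifest_path)
    invisible(res)
  }, error = on_fail)
}
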