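#' End-to-end species identification for one sample
#'
#' Orchestrates the full analysis: read the sample's reads, map them
#' competitively against every panel reference, apply the
#' mapping-quality filter and duplicate removal, compute per-reference
#' coverage/evenness evidence and normalized read counts, profile
#' terminal damage on the best-supported reference, call a consensus
#' mitogenome there, build a reference-anchored alignment of the
#' consensus with all panel references, place the sample in a
#' bootstrapped neighbor-joining tree rooted on the panel's outgroup,
#' and combine the three lines of evidence into a species call.
#'
#' The run is deterministic given `seed`. If `out_dir` is given, all
#' artifacts are written there: per-reference SAM, the evidence table
#' (`coverage.tsv`), damage profile (`damage.tsv`), consensus
#' (`consensus.fa`, `consensus.tsv`), the stripped alignment
#' (`msa.fa`), the rooted tree (`tree.nwk`), and the species call
#' (`call.json`).
#'
#' @param reads A reads tibble (`read_id`, `seq`) or a FASTQ path.
#' @param panel A `mito_panel`, or a FASTA path (then `annotations` must
#'   give the panel annotation TSV).
#' @param sample_id Label for the sample (also its tip label in the tree).
#' @param out_dir Output directory (created if missing), or `NULL` to
#'   skip writing artifacts.
#' @param cfg A [map_config()].
#' @param min_depth,consensus_threshold Consensus-calling thresholds.
#' @param n_boot Bootstrap replicates for the placement tree.
#' @param seed Seed for the bootstrap resampling.
#' @param annotations Panel annotation TSV when `panel` is a FASTA path.
#' @return A list of class `identify_run`: `call` (the `species_call`),
#'   `coverage`, `damage`, `lengths`, `consensus`, `msa`, `tree`,
#'   `best_ref`, `status` (0 when the verdict is concordant, 1
#'   otherwise), and `paths` (written artifacts, if any).
#' @export
run_identify <- function(reads, panel, sample_id = "sample",
                         out_dir = NULL, cfg = map_config(),
                         min_depth = 3, consensus_threshold = 0.5,
                         n_boot = 100, seed = 1, annotations = NULL) {
  if (is.character(reads)) reads <- read_fastq(reads)
  if (is.character(panel)) panel <- read_panel(panel, annotations)
  if (sample_id %in% panel$ref_id) {
    abort("sample_id collides with a panel reference id")
  }
  paths <- character(0)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(name) {
    if (is.null(out_dir)) return(NULL)
    p <- file.path(out_dir, name)
    paths[[name]] <<- p
    p
  }

  if (!nrow(reads)) {
    call <- structure(list(sample_id = sample_id, evidence = tibble(),
                           top_by_count = NA_character_,
                           top_by_evenness = NA_character_,
                           phylo_assignment = NA_character_,
                           verdict = "no_data", species = NA_character_,
                           notes = "empty read set"),
                      class = "species_call")
    p <- emit("call.json")
    if (!is.null(p)) .write_call_json(call, p)
    return(structure(list(call = call, status = 1L, paths = paths),
                     class = "identify_run"))
  }

  aln <- map_reads(reads, panel, cfg)
  ded <- dedup_alignments(filter_mapq(aln, cfg$mapq_min))
  cov <- normalized_counts(coverage_summary(ded, panel))

  if (all(cov$n_mapped == 0)) {
    call <- call_species(cov, panel, sample_id = sample_id)
    p <- emit("call.json")
    if (!is.null(p)) .write_call_json(call, p)
    return(structure(list(call = call, coverage = cov, status = 1L,
                          paths = paths),
                     class = "identify_run"))
  }

  cand <- cov[!cov$ref_id %in% panel$ref_id[panel$is_outgroup], ]
  best_ref <- if (nrow(cand) && any(cand$n_mapped > 0)) {
    cand$ref_id[which.max(cand$n_mapped)]
  } else {
    cov$ref_id[which.max(cov$n_mapped)]
  }

  damage <- damage_profile(ded, panel, best_ref)
  lengths <- length_summary(ded[ded$ref_id == best_ref, ])
  cons <- call_consensus(ded, panel, best_ref, min_depth = min_depth,
                         threshold = consensus_threshold)

  # reference-anchored alignment of consensus + full panel
  seqs <- setNames(panel$seq, panel$ref_id)
  seqs[[sample_id]] <- cons$seq
  entry <- panel_entry(panel, best_ref)
  msa <- anchor_msa(seqs, entry, include_anchor = FALSE)
  cr <- c(entry$cr_start, entry$cr_end)
  msa <- strip_columns(msa, remove_cr = !any(is.na(cr)), cr_interval = cr)

  tree <- NULL
  phylo_assign <- NA_character_
  outgroups <- panel$ref_id[panel$is_outgroup]
  if (nrow(msa$mat) >= 3 && ncol(msa$mat) >= 50) {
    tree <- tryCatch(
      bootstrap_support(msa, model = "K80", n_reps = n_boot, seed = seed),
      error = function(e) NULL)
    if (!is.null(tree) && length(outgroups)) {
      og <- intersect(outgroups, tree$tip.label)[1]
      if (!is.na(og)) tree <- root_with_outgroup(tree, og)
    }
    if (!is.null(tree)) {
      phylo_assign <- clade_of(tree, sample_id,
                               candidates = setdiff(panel$ref_id, outgroups))
    }
  }

  call <- call_species(cov, panel, phylo_assignment = phylo_assign,
                       sample_id = sample_id)

  if (!is.null(out_dir)) {
    for (rid in panel$ref_id) {
      write_sam(ded, panel, rid, emit(paste0(rid, ".sam")))
    }
    readr::write_tsv(as_tibble(cov), emit("coverage.tsv"))
    write_damage_profile(damage, emit("damage.tsv"))
    write_consensus(cons, emit("consensus.fa"), emit("consensus.tsv"),
                    id = sample_id)
    write_alignment(msa, emit("msa.fa"))
    if (!is.null(tree)) write_tree(tree, emit("tree.nwk"))
    .write_call_json(call, emit("call.json"))
  }

  structure(list(call = call, coverage = cov, damage = damage,
                 lengths = lengths, consensus = cons, msa = msa,
                 tree = tree, best_ref = best_ref,
                 status = if (call$verdict == "concordant") 0L else 1L,
                 paths = paths),
            class = "identify_run")
}

.write_call_json <- function(call, path) {
  x <- list(sample_id = call$sample_id, verdict = call$verdict,
            species = call$species, top_by_count = call$top_by_count,
            top_by_evenness = call$top_by_evenness,
            phylo_assignment = call$phylo_assignment,
            notes = as.list(call$notes),
            evidence = if (nrow(call$evidence)) as.data.frame(call$evidence) else list())
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.identify_run <- function(x, ...) {
  print(x$call)
  cat(sprintf("exit status: %d\n", x$status))
  invisible(x)
}
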