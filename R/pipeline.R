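#' Assemble a run configuration
#'
#' Thresholds default to the study's values: stringent alignment filter at
#' 99% identity and 1 kbp aligned length, pseudo-assembly merge overlap
#' 800 bp with 1 kbp minimum region, high-identity divergence cutoff 0.01
#' substitutions per base, MAPQ cutoff 20.
#'
#' @param genome,annotations,contigs,alignments,read_alignments,snps Input
#'   paths (FASTA, GFF3, FASTA, PAF/coords, SAM/BAM/TSV, VCF). Either these
#'   or `simulate` must be provided.
#' @param simulate Optional list describing a simulation instead of file
#'   inputs: `n_scaffolds`, `scaffold_length`, `families` (list of lists of
#'   [te_family()] arguments), plus optional `gene_density`, `read` (list of
#'   [read_sim_config()] arguments) and `failure_plan`.
#' @param thresholds Named list overriding the defaults.
#' @param seed Integer seed.
#' @param out_dir Output directory for the report and stage outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(genome = NULL, annotations = NULL, contigs = NULL,
                       alignments = NULL, read_alignments = NULL, snps = NULL,
                       simulate = NULL, thresholds = list(), seed = 1L,
                       out_dir = tempfile("repeatproof_run_")) {
  th <- utils::modifyList(
    list(min_identity = 0.99, min_len = 1000L, min_overlap = 800L,
         pseudo_min_len = 1000L, high_identity_div = 0.01, mapq = 20L,
         overlap_tolerance = 50L),
    thresholds
  )
  if (any(unlist(th[c("min_len", "min_overlap", "pseudo_min_len", "mapq")]) < 0) ||
      th$min_identity <= 0 || th$high_identity_div <= 0) {
    stop("thresholds must be positive")
  }
  cfg <- list(genome = genome, annotations = annotations, contigs = contigs,
              alignments = alignments, read_alignments = read_alignments,
              snps = snps, simulate = simulate, thresholds = th,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$simulate)) {
    paths <- cfg[c("genome", "annotations", "contigs", "alignments")]
    missing <- names(paths)[vapply(paths, is.null, TRUE)]
    if (length(missing) > 0) {
      stop("config incomplete: provide 'simulate' or paths for ",
           paste(missing, collapse = ", "))
    }
    paths <- c(paths, cfg[c("read_alignments", "snps")])
    paths <- paths[!vapply(paths, is.null, TRUE)]
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent) > 0) {
      stop("input path(s) do not exist: ", paste(absent, collapse = ", "))
    }
  }
  invisible(cfg)
}

#' Run the full evaluation pipeline
#'
#' Executes simulate/load, placement, assembly metrics, read evaluation,
#' gap analysis, feature assessment and the TE model in dependency order,
#' collecting every stage summary into a JSON-serializable run report.
#' A stage failure is recorded and aborts its dependents but not independent
#' stages.
#'
#' @param cfg A `run_config` (or path to a YAML config).
#' @return The run report (list), invisibly written to
#'   `file.path(cfg$out_dir, "report.json")`.
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  th <- cfg$thresholds
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("repeatproof")),
    seed = cfg$seed,
    thresholds = th,
    config_hash = config_hash(cfg),
    stages = list()
  )
  stage <- function(name, deps, fun) {
    failed <- vapply(deps, function(d) {
      !is.null(report$stages[[d]]$error)
    }, TRUE)
    if (any(failed)) {
      report$stages[[name]] <<- list(skipped = TRUE,
                                     reason = paste("dependency failed:",
                                                    paste(deps[failed], collapse = ", ")))
      return(invisible(NULL))
    }
    report$stages[[name]] <<- tryCatch(fun(), error = function(e) {
      list(error = conditionMessage(e))
    })
  }

  env <- new.env()
  stage("inputs", character(0), function() {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      fams <- lapply(sim$families, function(f) do.call(te_family, f))
      env$genome <- generate_genome(
        n_scaffolds = sim$n_scaffolds,
        scaffold_length = sim$scaffold_length,
        families = fams,
        gene_density = if (is.null(sim$gene_density)) 10 else sim$gene_density,
        seed = cfg$seed
      )
      read_args <- if (is.null(sim$read)) list() else sim$read
      read_args$seed <- cfg$seed
      env$read_cfg <- do.call(read_sim_config, read_args)
      env$reads <- simulate_reads(env$genome, env$read_cfg)
      plan <- if (is.null(sim$failure_plan)) list() else sim$failure_plan
      plan$seed <- cfg$seed
      sc <- simulate_contigs(env$genome, plan)
      env$contigs <- sc$contigs
      env$blocks <- sc$blocks
      env$truth <- sc$truth
      env$read_aln <- env$reads$alignments
      write_simulation(env$genome, file.path(cfg$out_dir, "sim"),
                       reads = env$reads, contigs = sc)
      list(mode = "simulated",
           genome_bp = sum(Biostrings::width(env$genome$seqs)),
           n_genes = nrow(env$genome$genes), n_tes = nrow(env$genome$tes),
           n_reads = length(env$reads$reads), n_contigs = length(env$contigs))
    } else {
      env$ref_seqs <- Biostrings::readDNAStringSet(cfg$genome)
      names(env$ref_seqs) <- sub("\\s.*", "", names(env$ref_seqs))
      feats <- read_features(cfg$annotations)
      env$genome <- list(seqs = env$ref_seqs,
                         genes = feats[feats$feature_type == "gene", ],
                         tes = cbind(feats[feats$feature_type == "TE", ],
                                     n_subs = NA_integer_, tandem_pair = NA_integer_))
      class(env$genome) <- "genome_bundle"
      env$contigs <- Biostrings::readDNAStringSet(cfg$contigs)
      names(env$contigs) <- sub("\\s.*", "", names(env$contigs))
      ext <- tolower(tools::file_ext(cfg$alignments))
      env$blocks <- if (ext == "paf") read_paf(cfg$alignments) else
        read_coords(cfg$alignments)
      env$read_aln <- if (!is.null(cfg$read_alignments))
        read_read_alignments(cfg$read_alignments) else NULL
      list(mode = "files",
           genome_bp = sum(Biostrings::width(env$genome$seqs)),
           n_contigs = length(env$contigs),
           n_blocks = nrow(env$blocks))
    }
  })

  stage("placement", "inputs", function() {
    env$ref_lengths <- stats::setNames(Biostrings::width(env$genome$seqs),
                                       names(env$genome$seqs))
    pl <- best_placements(env$blocks, th$overlap_tolerance)
    env$placements <- stringent_filter(pl, th$min_identity, th$min_len)
    frac <- genome_fraction_and_duplication(env$placements, env$ref_lengths)
    env$genome_fraction <- frac
    list(n_contigs_placed = length(env$placements),
         n_dropped = length(attr(env$placements, "dropped")),
         genome_fraction = frac$genome_fraction,
         duplication_ratio = frac$duplication_ratio)
  })

  stage("assembly_metrics", "placement", function() {
    m <- assembly_metrics(env$contigs,
                          genome_size = sum(env$ref_lengths))
    na <- na_metrics(env$placements, 50, genome_size = sum(env$ref_lengths))
    err <- per100kbp_errors(env$placements, env$contigs, env$genome$seqs)
    c(m, list(NA50 = na$N, LA50 = na$L,
              n_misassemblies = nrow(na$events),
              mismatches_per_100kbp = err$mismatches_per_100kbp,
              short_indels_per_100kbp = err$short_indels_per_100kbp,
              long_indels_per_100kbp = err$long_indels_per_100kbp))
  })

  stage("read_eval", "placement", function() {
    if (is.null(env$read_aln)) return(list(skipped = TRUE,
                                           reason = "no read alignments"))
    prof <- profile_errors(env$read_aln, mapq_min = 0L)
    depth <- depth_of_coverage(env$read_aln, env$ref_lengths,
                               mapq_min = 0L)
    env$depth <- depth
    list(mismatch_rate = prof$totals$mismatch_rate,
         insertion_rate = prof$totals$insertion_rate,
         deletion_rate = prof$totals$deletion_rate,
         mean_depth = depth$mean_depth,
         per_scaffold_depth = depth$per_scaffold)
  })

  stage("gaps", "placement", function() {
    g <- alignment_gaps(env$placements, env$ref_lengths)
    env$gaps <- g
    cov_gaps <- NULL
    pseudo <- NULL
    if (!is.null(env$read_aln)) {
      pseudo <- pseudo_assemble(env$read_aln, th$min_overlap,
                                th$pseudo_min_len)
      cov_gaps <- alignment_gaps(pseudo, env$ref_lengths)
    }
    content <- if (nrow(g) > 0 && nrow(env$genome$tes) > 0) {
      gap_content(g, env$genome, explained_by = cov_gaps)
    } else NULL
    list(n_gaps = nrow(g),
         total_gap_bp = sum(g$length),
         mean_gap_gc = if (!is.null(content)) content$mean_gc else NA,
         te_gap_fraction = if (!is.null(content))
           unname(content$fraction_by_class["TE"]) else NA,
         n_pseudo_contigs = if (!is.null(pseudo)) nrow(pseudo) else NA,
         pseudo_n50 = if (!is.null(pseudo) && nrow(pseudo) > 0)
           nx_metrics(pseudo$length)$N else NA,
         fraction_gaps_explained_by_coverage = if (!is.null(content))
           content$fraction_gaps_explained_by_coverage else NULL)
  })

  stage("assessment", "placement", function() {
    res <- assess_all(env$genome, env$placements, env$contigs)
    env$assessments <- res$table
    utils::write.table(res$table,
                       file.path(cfg$out_dir, "feature_assessments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$summary
  })

  stage("te_glmm", "assessment", function() {
    design <- build_design(env$assessments, env$genome,
                           high_identity_div = th$high_identity_div)
    fit <- fit_glmm(design)
    list(coefficients = data.frame(term = names(fit$beta),
                                   estimate = unname(fit$beta),
                                   se = unname(fit$se),
                                   z = unname(fit$z), p = unname(fit$p)),
         sigma_family = fit$sigma_family, loglik = fit$loglik)
  })

  path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  report$path <- path
  invisible(report)
}

config_hash <- function(cfg) {
  x <- cfg[setdiff(names(cfg), "out_dir")]
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE)
  # tiny stable FNV-1a hash; avoids a digest dependency. 32-bit state is
  # kept as a double and split at 16 bits so xor and the modular multiply
  # stay exact (bitwXor would overflow to NA at 2^31).
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b)
    h <- ((((h %/% 65536) * 16777619) %% 65536) * 65536 +
            (h %% 65536) * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
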