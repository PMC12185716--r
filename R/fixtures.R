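#' Emit joint VCF, PED, read-evidence and mask fixtures from a truth set
#'
#' Every simulated mutation becomes a joint-VCF record in which the child
#' is a confident heterozygote and both parents confident hom-ref with no
#' alt-supporting reads (`AC=1`). Per offspring, additional negative
#' records are spiked so each detection filter is exercised in isolation:
#' a borderline parental likelihood (fails the de novo score), a
#' low-depth child call, a parent with 2 alt-supporting reads, an
#' `AC=2` site carried by an unrelated sample, and inherited background
#' hets (`AC>=2`). Read-evidence rows link each true DNM whose nearest
#' informative site lies within the cohort read length to that site, with
#' parental genotypes consistent with the simulated origin. Artifact
#' clusters are covered by the repeat mask with the configured
#' probability.
#'
#' @param truth A `truth_set` from [simulate_mutations()].
#' @param config The generating `sim_config`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for read depths, spike placement and masks.
#' @param n_background Inherited background variants per offspring.
#' @return List with the file paths (`vcf`, `ped`, `meta`, `evidence`,
#'   `repeat_bed`, `mapability_bed`, `truth_dnms`, `truth_clusters`) and
#'   record counts.
#' @export
emit_fixtures <- function(truth, config, dir, seed = config$seed + 2L,
                          n_background = 3L) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- truth$meta
  children <- meta$sample_id
  fathers <- paste0(children, "_fa")
  mothers <- paste0(children, "_mo")
  samples <- c(rbind(fathers, mothers, children))

  # --- PED ---
  ped_path <- file.path(dir, "cohort.ped")
  ped_lines <- unlist(lapply(seq_along(children), function(i) {
    fam <- meta$family_id[i]
    c(paste(fam, fathers[i], 0, 0, 1, 0),
      paste(fam, mothers[i], 0, 0, 2, 0),
      paste(fam, children[i], fathers[i], mothers[i], 1, 0))
  }))
  writeLines(ped_lines, ped_path)

  # --- record table: truth DNMs + spiked negatives + background ---
  dn <- truth$dnms
  rec <- data.frame(chrom = dn$chrom, pos = dn$pos, ref = dn$ref, alt = dn$alt,
                    child = dn$sample_id, type = "dnm", ac = 1L,
                    stringsAsFactors = FALSE)
  used <- paste(rec$chrom, rec$pos)
  draw_pos <- function(n) {
    chrom <- sample(names(config$genome), n, replace = TRUE,
                    prob = config$genome / sum(config$genome))
    pos <- floor(stats::runif(n, 1, config$genome[chrom] - 1000)) + 1L
    k <- paste(chrom, pos)
    while (any(k %in% used) || anyDuplicated(k)) {
      redo <- (k %in% used) | duplicated(k)
      pos[redo] <- floor(stats::runif(sum(redo), 1,
                                      config$genome[chrom[redo]] - 1000)) + 1L
      k <- paste(chrom, pos)
    }
    used <<- c(used, k)
    data.frame(chrom = chrom, pos = as.integer(pos), stringsAsFactors = FALSE)
  }
  spike_types <- c("spike_score", "spike_depth", "spike_parental", "spike_ac")
  n_child <- length(children)
  spikes <- do.call(rbind, lapply(spike_types, function(tp) {
    p <- draw_pos(n_child)
    al <- .random_snv(n_child)
    data.frame(chrom = p$chrom, pos = p$pos, ref = al$ref, alt = al$alt,
               child = children, type = tp,
               ac = ifelse(tp == "spike_ac", 2L, 1L),
               stringsAsFactors = FALSE)
  }))
  bg <- NULL
  if (n_background > 0L) {
    nb <- n_background * n_child
    p <- draw_pos(nb)
    al <- .random_snv(nb)
    bg <- data.frame(chrom = p$chrom, pos = p$pos, ref = al$ref, alt = al$alt,
                     child = rep(children, each = n_background),
                     type = "background", ac = 2L, stringsAsFactors = FALSE)
  }
  rec <- rbind(rec, spikes, bg)
  chrom_order <- base::match(rec$chrom, names(config$genome))
  ord <- order(chrom_order, rec$pos)
  rec <- rec[ord, , drop = FALSE]

  # --- genotype matrix ---
  n_rec <- nrow(rec)
  clean_ref <- "0/0:30,0:30:0,90,180"
  gm <- matrix(clean_ref, nrow = n_rec, ncol = length(samples),
               dimnames = list(NULL, samples))
  ci <- base::match(rec$child, samples)
  fi <- base::match(paste0(rec$child, "_fa"), samples)
  mi <- base::match(paste0(rec$child, "_mo"), samples)
  d <- sample(20:40, n_rec, replace = TRUE)
  a <- pmax(pmin(stats::rbinom(n_rec, d, 0.5), d - 5L), 5L)
  het_child <- paste0("0/1:", d - a, ",", a, ":", d, ":", 3L * d, ",0,", 3L * d)
  het_other <- "0/1:15,15:30:60,0,60"

  idx <- function(type) which(rec$type == type)
  i <- idx("dnm")
  gm[cbind(i, ci[i])] <- het_child[i]
  i <- idx("spike_score")  # father likelihood barely favours het; 1 alt read
  gm[cbind(i, ci[i])] <- het_child[i]
  gm[cbind(i, fi[i])] <- "0/0:29,1:30:10,0,40"
  i <- idx("spike_depth")  # child depth below the threshold
  gm[cbind(i, ci[i])] <- "0/1:4,4:8:24,0,24"
  i <- idx("spike_parental")  # 2 alt reads in the father, clean likelihoods
  gm[cbind(i, ci[i])] <- het_child[i]
  gm[cbind(i, fi[i])] <- "0/0:28,2:30:0,90,180"
  i <- idx("spike_ac")  # unrelated carrier lifts the joint AC to 2
  gm[cbind(i, ci[i])] <- het_child[i]
  carrier <- base::match(fathers[(base::match(rec$child[i], children) %% n_child) + 1L],
                         samples)
  gm[cbind(i, carrier)] <- het_other
  i <- idx("background")  # inherited from a het father
  gm[cbind(i, ci[i])] <- het_child[i]
  gm[cbind(i, fi[i])] <- het_other

  # --- VCF ---
  vcf_path <- file.path(dir, "cohort.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cdnmkit_simulator",
    paste0("##contig=<ID=", names(config$genome), ",length=",
           format(config$genome, scientific = FALSE, trim = TRUE), ">"),
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Joint allele count\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fixed <- paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt, ".", "PASS",
                 paste0("AC=", rec$ac), "GT:AD:DP:PL", sep = "\t")
  body <- do.call(paste, c(list(fixed),
                           lapply(seq_along(samples), function(j) gm[, j]),
                           list(sep = "\t")))
  writeLines(c(header, body), vcf_path)

  # --- read evidence for true DNMs ---
  dn_true <- dn[!dn$is_artifact, , drop = FALSE]
  rl <- meta$read_length[base::match(dn_true$sample_id, meta$sample_id)]
  d_inf <- sample(10:300, nrow(dn_true), replace = TRUE)
  phaseable <- d_inf <= rl
  ev <- NULL
  if (any(phaseable)) {
    dv <- dn_true[phaseable, , drop = FALSE]
    di <- d_inf[phaseable]
    side <- sample(c(-1L, 1L), nrow(dv), replace = TRUE)
    n_reads <- sample(2:4, nrow(dv), replace = TRUE)
    ev <- data.frame(
      sample_id = rep(dv$sample_id, n_reads),
      chrom = rep(dv$chrom, n_reads),
      pos = rep(dv$pos, n_reads),
      alt = rep(dv$alt, n_reads),
      read_id = paste0("r", unlist(lapply(n_reads, seq_len)), "_",
                       rep(seq_len(nrow(dv)), n_reads)),
      dnm_allele = "alt",
      inf_chrom = rep(dv$chrom, n_reads),
      inf_pos = rep(dv$pos + side * di, n_reads),
      informative_allele = "alt",
      father_gt = rep(ifelse(dv$origin == "paternal", "0/1", "0/0"), n_reads),
      mother_gt = rep(ifelse(dv$origin == "maternal", "0/1", "0/0"), n_reads),
      stringsAsFactors = FALSE
    )
  } else {
    ev <- data.frame(sample_id = character(), chrom = character(),
                     pos = integer(), alt = character(), read_id = character(),
                     dnm_allele = character(), inf_chrom = character(),
                     inf_pos = integer(), informative_allele = character(),
                     father_gt = character(), mother_gt = character(),
                     stringsAsFactors = FALSE)
  }
  ev_path <- file.path(dir, "evidence.tsv")
  utils::write.table(ev, ev_path, sep = "\t", quote = FALSE, row.names = FALSE)

  # --- masks ---
  cl <- truth$clusters
  rep_iv <- NULL
  map_iv <- NULL
  if (nrow(cl) > 0L) {
    art <- cl[cl$is_artifact, , drop = FALSE]
    in_rep <- stats::runif(nrow(art)) < config$artifact_in_repeat
    if (any(in_rep)) {
      rep_iv <- data.frame(chrom = art$chrom[in_rep],
                           start = pmax(art$start[in_rep] - 11L, 0L),
                           end = art$end[in_rep] + 10L)
    }
    in_map <- stats::runif(nrow(art)) < 0.2
    if (any(in_map)) {
      map_iv <- data.frame(chrom = art$chrom[in_map],
                           start = pmax(art$start[in_map] - 11L, 0L),
                           end = art$end[in_map] + 10L)
    }
  }
  rand_iv <- function(n) {
    chrom <- sample(names(config$genome), n, replace = TRUE)
    start <- floor(stats::runif(n, 0, config$genome[chrom] - 2000))
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(start + sample(200:1000, n, replace = TRUE)))
  }
  repeat_mask <- genome_mask(rbind(rep_iv, rand_iv(50L)), label = "repeat")
  map_mask <- genome_mask(rbind(map_iv, rand_iv(30L)), label = "low_mapability")
  rep_path <- file.path(dir, "repeats.bed")
  map_path <- file.path(dir, "mapability.bed")
  write_mask(repeat_mask, rep_path)
  write_mask(map_mask, map_path)

  meta_path <- file.path(dir, "meta.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  td_path <- file.path(dir, "truth_dnms.tsv")
  tc_path <- file.path(dir, "truth_clusters.tsv")
  utils::write.table(truth$dnms, td_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$clusters, tc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(vcf = vcf_path, ped = ped_path, meta = meta_path, evidence = ev_path,
       repeat_bed = rep_path, mapability_bed = map_path,
       truth_dnms = td_path, truth_clusters = tc_path,
       n_records = n_rec, n_samples = length(samples),
       n_true_dnms = nrow(dn), n_evidence_rows = nrow(ev))
}
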