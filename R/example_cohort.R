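# Bundled reference cohorts: a 58-patient prospective-style HLH cohort
# and a 13-sample validation set. Both are constructed fully in code so
# the package's worked examples, regression tests and reproduction
# script need no external data. Mutation HGVS strings are well-known
# HLH alleles from the clinical literature; sample-level assignments,
# ages and triggers are an illustrative encoding with the summary
# structure typical of a prospective HLH cohort (diagnostic yield
# concentrated in infancy, secondary triggers among the undiagnosed).

.gene_origin <- function(gene) {
  genes <- hlh_panel_genes()
  i <- match(gene, genes$gene)
  1e6L + i * 2e6L
}

#' Bundled example HLH cohort (58 patients)
#'
#' A fully worked diagnostic cohort: patient metadata, annotated
#' variants with per-patient genotypes, an externally typed structural
#' allele (a known UNC13D intronic inversion detected by a dedicated
#' PCR assay), and specifications of two large exonic deletions (a
#' homozygous STX11 deletion and a hemizygous XIAP deletion) to be
#' planted in simulated coverage and recovered by the CNV caller.
#'
#' Of the 58 patients, 22 carry genotypes that complete a molecular
#' diagnosis under the panel's inheritance logic, and 9 of the
#' remaining 36 carry a single damaging-predicted monoallelic variant
#' (variants of unknown significance). All patients carry common
#' background polymorphisms that the filter cascade removes.
#'
#' @return List with `patients`, `variants`, `genotypes`,
#'   `external_alleles`, `deletion_specs` (tibble usable as the
#'   `deletions` field of [coverage_sim_config()]).
#' @export
hlh_example_cohort <- function() {
  diagnosed_infant <- c("P1", "P2", "P9", "P10", "P16", "P17", "P19", "P20",
                        "P22", "P26", "P35", "P37", "P38")
  ages <- c(
    # diagnosed
    P1 = 0.5, P2 = 0.8, P9 = 0.3, P10 = 0.6, P16 = 0.2, P17 = 0.9,
    P19 = 0.4, P20 = 0.7, P22 = 0.3, P26 = 0.8, P35 = 0.5, P37 = 0.6,
    P38 = 0.25,
    P39 = 2, P40 = 3, P41 = 1.5, P50 = 4,
    P11 = 7, P53 = 6, P56 = 8, P58 = 10,
    P48 = 16,
    # undiagnosed
    P3 = 0.4, P4 = 0.6, P5 = 0.9, P6 = 0.2, P7 = 0.7, P8 = 0.5, P12 = 0.3,
    P13 = 2, P14 = 3, P15 = 1.2, P18 = 4, P21 = 2.5, P23 = 1.8, P24 = 3.5,
    P25 = 4.5,
    P27 = 6, P28 = 9, P29 = 11, P30 = 7, P31 = 5.5,
    P32 = 13, P33 = 15, P34 = 17, P36 = 12.5, P42 = 14, P43 = 16.5,
    P44 = 13.5,
    P45 = 25, P46 = 30, P47 = 40, P49 = 22, P51 = 55, P52 = 70, P54 = 19,
    P55 = 35,
    P57 = NA
  )
  ids <- names(ages)
  males <- c("P26", paste0("P", seq(1, 53, by = 2)))
  trigger <- setNames(rep("none", length(ids)), ids)
  trigger[c("P2", "P10")] <- "EBV"
  trigger[c("P22", "P50")] <- "other_infection"
  trigger[c("P3", "P4", "P5", "P6", "P7", "P8", "P12", "P13", "P14", "P15")] <- "EBV"
  trigger[c("P18", "P21", "P23", "P24")] <- "other_infection"
  trigger[c("P45", "P46", "P47")] <- "malignancy"
  trigger[c("P49", "P51", "P52", "P54", "P27")] <- "autoimmune"
  albinism <- setNames(rep("no", length(ids)), ids)
  albinism[c("P1", "P2", "P22", "P41", "P53", "P28")] <- "yes"
  fam <- setNames(rep("no", length(ids)), ids)
  fam[c("P16", "P40", "P9", "P38", "P29", "P30", "P31", "P13")] <- "yes"
  consang <- setNames(rep("no", length(ids)), ids)
  consang[c("P1", "P9", "P16", "P17", "P20", "P22", "P35", "P37", "P38",
            "P39", "P40", "P41", "P53", "P58",
            "P3", "P6", "P13", "P21", "P27", "P29", "P31", "P36", "P44",
            "P52")] <- "yes"

  patients <- tibble::tibble(
    patient_id = ids,
    age_at_diagnosis = unname(ages),
    age_bin = age_bin(unname(ages)),
    sex = ifelse(ids %in% males, "M", "F"),
    consanguinity = unname(consang),
    albinism = unname(albinism),
    family_history = unname(fam),
    trigger = unname(trigger)
  )

  v <- function(gene, off, ref, alt, cons, hc, hp, maf, sift, poly, cadd) {
    genes <- hlh_panel_genes()
    chrom <- genes$chromosome[genes$gene == gene]
    tibble::tibble(chromosome = chrom,
                   position = .gene_origin(gene) + off,
                   ref = ref, alt = alt, gene = gene, consequence = cons,
                   hgvs_c = hc, hgvs_p = hp, maf = maf, sift_pred = sift,
                   polyphen_pred = poly, cadd = cadd)
  }
  DAM <- list(s = "deleterious", p = "probably_damaging")
  variants <- dplyr::bind_rows(
    # causal small variants
    v("PRF1",   272L, "C", "T", "missense", "c.272C>T", "p.Ala91Val",
      0.035, DAM$s, "possibly_damaging", 23),
    v("PRF1",  1288L, "G", "T", "missense", "c.1288G>T", "p.Asp430Tyr",
      0, DAM$s, DAM$p, 27),
    v("PRF1",   659L, "G", "A", "missense", "c.659G>A", "p.Gly220Asp",
      0, DAM$s, DAM$p, 26),
    v("PRF1",   673L, "C", "T", "missense", "c.673C>T", "p.Arg225Trp",
      1e-4, DAM$s, DAM$p, 29),
    v("PRF1",  1122L, "G", "A", "stop_gained", "c.1122G>A", "p.Trp374*",
      1e-4, NA, NA, 36),
    v("PRF1",  1349L, "C", "T", "missense", "c.1349C>T", "p.Thr450Met",
      2e-4, DAM$s, DAM$p, 25),
    v("PRF1",  1179L, "C", "A", "stop_gained", "c.1179C>A", "p.Cys393*",
      0, NA, NA, 38),
    v("PRF1",  1434L, "G", "T", "missense", "c.1434G>T", "p.Leu478Arg",
      0, DAM$s, DAM$p, 28),
    v("UNC13D", 569L, "G", "A", "splice_region", "c.569+5G>A", NA,
      0, NA, NA, 22),
    v("UNC13D", 570L, "G", "A", "splice_acceptor", "c.570-1G>A", NA,
      0, NA, NA, 34),
    v("UNC13D", 753L, "G", "T", "splice_donor", "c.753+1G>T", NA,
      0, NA, NA, 33),
    v("UNC13D", 2236L, "C", "T", "stop_gained", "c.2236C>T", "p.Gln746*",
      0, NA, NA, 40),
    v("UNC13D", 2346L, "CAGAG", "C", "frameshift", "c.2346_2349del",
      "p.Arg748Serfs*12", 0, NA, NA, 35),
    v("UNC13D", 2709L, "T", "A", "splice_donor", "c.2709+2T>A", NA,
      0, NA, NA, 33),
    v("UNC13D", 2544L, "CT", "C", "frameshift", "c.2544delT",
      "p.Ile848Metfs*67", 0, NA, NA, 34),
    v("STX11",  369L, "GTTTGAGGC", "GTGG", "frameshift", "c.369_376delinsTGG",
      "p.Val124Glyfs*60", 0, NA, NA, 33),
    v("LYST",  9107L, "CTTTGA", "C", "splice_region", "c.9107-20_9109del", NA,
      0, NA, DAM$p, 24),
    v("LYST",  2749L, "CAG", "C", "frameshift", "c.2749_2750del",
      "p.Arg917Glyfs*5", 0, NA, NA, 35),
    v("RAB27A", 148L, "AG", "C", "frameshift", "c.148_149delinsC",
      "p.Arg50Glnfs*35", 0, NA, NA, 32),
    v("RAB27A", 514L, "GTTACA", "G", "frameshift", "c.514_518del",
      "p.Gln172Asnfs*2", 0, NA, NA, 33),
    # monoallelic VUS variants
    v("STXBP2", 1034L, "C", "T", "missense", "c.1034C>T", "p.Thr345Met",
      0.002, DAM$s, DAM$p, 24),
    v("UNC13D", 2588L, "G", "A", "missense", "c.2588G>A", "p.Gly863Asp",
      0.004, DAM$s, "possibly_damaging", 23),
    v("LYST",  4189L, "T", "C", "missense", "c.4189T>C", "p.Phe1397Leu",
      0.003, DAM$s, DAM$p, 22),
    v("STX11",  616L, "G", "A", "missense", "c.616G>A", "p.Glu206Lys",
      0.001, "tolerated", DAM$p, 21),
    v("AP3B1", 1037L, "A", "G", "missense", "c.1037A>G", "p.Glu346Gly",
      0.002, DAM$s, DAM$p, 23),
    v("RAB27A", 239L, "G", "A", "missense", "c.239G>A", "p.Arg80Gln",
      0.001, DAM$s, "possibly_damaging", 24),
    # common background polymorphisms (removed by the cascade)
    v("PRF1",   900L, "A", "G", "missense", "c.900A>G", "p.Lys300Glu",
      0.30, "tolerated", "benign", 3),
    v("UNC13D", 1977L, "C", "T", "synonymous", "c.1977C>T", NA,
      0.45, NA, NA, 1),
    v("STXBP2",  56L, "A", "G", "intronic", "c.56-20A>G", NA,
      0.22, NA, NA, 1),
    v("LYST",  11000L, "G", "A", "UTR", "c.*110G>A", NA,
      0.18, NA, NA, 1),
    v("ITK",    321L, "T", "C", "missense", "c.321T>C", "p.Ser107Pro",
      0.09, "tolerated", "benign", 5)
  )
  variants$variant_id <- paste(variants$chromosome, variants$position,
                               variants$ref, variants$alt, sep = ":")
  vid <- setNames(variants$variant_id, variants$hgvs_c)

  gt <- function(pid, hgvs, zyg) {
    tibble::tibble(sample_id = pid, variant_id = unname(vid[hgvs]),
                   zygosity = zyg)
  }
  genotypes <- dplyr::bind_rows(
    gt("P48", "c.272C>T", "het"), gt("P48", "c.1288G>T", "het"),
    gt("P20", "c.659G>A", "hom"),
    gt("P35", "c.673C>T", "hom"),
    gt("P16", "c.1122G>A", "hom"), gt("P40", "c.1122G>A", "hom"),
    gt("P17", "c.1349C>T", "hom"),
    gt("P19", "c.1179C>A", "het"), gt("P19", "c.1434G>T", "het"),
    gt("P11", "c.569+5G>A", "het"),
    gt("P1", "c.570-1G>A", "hom"),
    gt("P37", "c.753+1G>T", "hom"),
    gt("P10", "c.2236C>T", "het"), gt("P10", "c.2346_2349del", "het"),
    gt("P50", "c.2709+2T>A", "hom"),
    gt("P58", "c.2544delT", "hom"),
    gt("P9", "c.369_376delinsTGG", "hom"),
    gt("P38", "c.369_376delinsTGG", "hom"),
    gt("P39", "c.369_376delinsTGG", "hom"),
    gt("P2", "c.9107-20_9109del", "hom"),
    gt("P22", "c.2749_2750del", "hom"),
    gt("P53", "c.148_149delinsC", "hom"),
    gt("P41", "c.514_518del", "hom"),
    # monoallelic VUS carriers (9 patients, 7 distinct variants)
    gt("P13", "c.272C>T", "het"), gt("P13", "c.1034C>T", "het"),
    gt("P27", "c.272C>T", "het"),
    gt("P42", "c.272C>T", "het"),
    gt("P28", "c.2588G>A", "het"), gt("P32", "c.2588G>A", "het"),
    gt("P44", "c.4189T>C", "het"),
    gt("P46", "c.616G>A", "het"),
    gt("P36", "c.1037A>G", "het"),
    gt("P55", "c.239G>A", "het"),
    # common polymorphisms spread across the cohort
    dplyr::bind_rows(lapply(ids, function(p) dplyr::bind_rows(
      gt(p, "c.900A>G", "het"),
      gt(p, "c.1977C>T", "het"),
      gt(p, "c.56-20A>G", "hom")
    ))),
    dplyr::bind_rows(lapply(ids[seq(1, length(ids), by = 3)], function(p)
      gt(p, "c.*110G>A", "het"))),
    dplyr::bind_rows(lapply(ids[seq(2, length(ids), by = 4)], function(p)
      gt(p, "c.321T>C", "het")))
  )

  external_alleles <- tibble::tibble(
    patient_id = "P11", gene = "UNC13D", allele = "intron1_inversion",
    zygosity = "het"
  )
  deletion_specs <- tibble::tibble(
    sample_id = c("P56", "P26"),
    gene = c("STX11", "XIAP"),
    first_amplicon = c(5L, 1L),
    n_amplicons = c(8L, 13L),
    zygosity = c("hom", "hemi")
  )
  list(patients = patients, variants = variants, genotypes = genotypes,
       external_alleles = external_alleles, deletion_specs = deletion_specs)
}

#' Bundled validation truth and call sets (13 samples, 74 variants)
#'
#' Thirteen samples with previously established molecular diagnoses:
#' 18 small disease-causing mutations plus 56 exonic polymorphisms form
#' the truth set for sensitivity evaluation. The call set misses two of
#' the 74: a homozygous RAB27A indel lying in a homopolymer stretch
#' (miscalled by the upstream caller) and one polymorphism. A
#' homozygous STXBP2 exon-2 deletion carried by one sample is a
#' structural record outside the small-variant truth set (it is found
#' by coverage analysis, not by variant calling). The polymorphism
#' records are synthetic placeholders; only their count enters the
#' sensitivity computation.
#'
#' @return List with `truth`, `called` (tibbles keyed by `sample_id`,
#'   `chromosome`, `position`, `ref`, `alt`) and `structural` (the
#'   deletion record).
#' @export
hlh_validation_set <- function() {
  mut <- tibble::tribble(
    ~sample_id, ~gene, ~offset, ~ref, ~alt, ~hgvs_c, ~zygosity,
    "V01", "PRF1",    272L, "C", "T", "c.272C>T", "het",
    "V01", "PRF1",    797L, "T", "C", "c.797T>C", "het",
    "V02", "UNC13D", 2135L, "GATC", "G", "c.2135_2137del", "het",
    "V02", "UNC13D", 2346L, "CAGAG", "C", "c.2346_2349del", "het",
    "V03", "UNC13D", 1388L, "A", "C", "c.1388A>C", "het",
    "V03", "UNC13D",  118L, "G", "A", "c.118-307G>A", "het",
    "V04", "UNC13D", 2719L, "C", "CAGTC", "c.2719_2722dup", "het",
    "V04", "UNC13D", 1992L, "G", "C", "c.1992+1G>C", "het",
    "V06", "STXBP2",   56L, "T", "C", "c.56T>C", "het",
    "V06", "STXBP2",  704L, "G", "C", "c.704G>C", "het",
    "V07", "XIAP",    877L, "G", "A", "c.877G>A", "hemi",
    "V08", "XIAP",   1141L, "C", "T", "c.1141C>T", "hemi",
    "V09", "RAB27A",  148L, "AG", "C", "c.148_149delinsC", "hom",
    "V10", "RAB27A",  514L, "GTTACA", "G", "c.514_518del", "hom",
    "V11", "LYST",   2311L, "C", "T", "c.2311C>T", "hom",
    "V12", "LYST",   1902L, "C", "CA", "c.1902dup", "hom",
    "V13", "AP3B1",  1254L, "C", "CA", "c.1254dup", "het",
    "V13", "AP3B1",  2626L, "C", "T", "c.2626C>T", "het"
  )
  genes <- hlh_panel_genes()
  mut$chromosome <- genes$chromosome[match(mut$gene, genes$gene)]
  mut$position <- vapply(seq_len(nrow(mut)), function(i)
    .gene_origin(mut$gene[i]) + mut$offset[i], double(1))
  mut$class <- "mutation"

  # 56 synthetic exonic polymorphisms cycled over the 13 samples
  samp <- sprintf("V%02d", 1:13)
  poly_genes <- rep_len(c("PRF1", "UNC13D", "STXBP2", "LYST", "AP3B1",
                          "STX11", "ITK"), 56)
  poly <- tibble::tibble(
    sample_id = rep_len(samp, 56),
    gene = poly_genes,
    chromosome = genes$chromosome[match(poly_genes, genes$gene)],
    position = vapply(seq_len(56), function(i)
      .gene_origin(poly_genes[i]) + 5000 + i * 13, double(1)),
    ref = "A", alt = "G",
    hgvs_c = sprintf("poly_%02d", 1:56),
    zygosity = rep_len(c("het", "hom"), 56),
    class = "polymorphism"
  )
  truth <- dplyr::bind_rows(
    mut[, c("sample_id", "gene", "chromosome", "position", "ref", "alt",
            "hgvs_c", "zygosity", "class")],
    poly
  )
  missed <- truth$hgvs_c %in% c("c.148_149delinsC", "poly_56")
  called <- truth[!missed, ]
  structural <- tibble::tibble(
    sample_id = "V05", gene = "STXBP2", description = "exon 2 deletion (298 bp)",
    zygosity = "hom"
  )
  list(truth = truth, called = called, structural = structural)
}
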