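fx <- kif7_allele_fixtures()
region <- fx$region
wt <- fx$sequences[["wild-type"]]

test_that("packaged fixtures carry the kif7 target region and alleles", {
  expect_identical(wt, "ATCCAAATTCCATTTTGTGGACCTGGCAGGATCAGAG")
  expect_identical(fx$sequences[["i271"]],
                   "ATCCAAATTCCATTTTGTCAGGATCAGAGCGCATCCTTAA")
  expect_identical(fx$sequences[["i273"]],
                   "ATCCAAATTCCATTTTGTCCTGGCAGGATCAGAG")
  expect_identical(region$cds_start_nt, 729L)
  expect_identical(region$frame_offset, 1L)
  expect_identical(region$first_residue_number, 244L)
})

test_that("translation in the anchored frame reproduces the allele table", {
  expect_identical(translate_region(region), "SKFHFVDLAGSE")
  expect_identical(translate_region(region, fx$sequences[["i271"]]),
                   "SKFHFVRIRAHP*")
  expect_identical(translate_region(region, fx$sequences[["i273"]]),
                   "SKFHFVLAGSE")
  # trailing partial codons are dropped: adding 1-2 bases changes nothing
  expect_identical(translate_region(region, paste0(wt, "A")),
                   "SKFHFVDLAGSE")
  expect_error(translate_region(region, "ATCCAANTT"), "position 7")
})

test_that("single-indel calls recover the engineered deletions", {
  cases <- list(
    list(name = "i271", len = 8L, allele = "GGACCTGG", pos = 747L),
    list(name = "i272", len = 7L, allele = "TTGTGGA", pos = 743L),
    list(name = "i273", len = 3L, allele = "GGA", pos = 747L))
  for (cs in cases) {
    call <- call_indel(region, fx$sequences[[cs$name]])
    expect_identical(call$kind, "deletion")
    expect_identical(call$length_nt, cs$len)
    expect_identical(call$ref_allele, cs$allele)
    expect_identical(call$position_nt, cs$pos)
    # applying the call reconstructs the mutant over the covered region
    applied <- apply_indel(region, call)
    m <- fx$sequences[[cs$name]]
    expect_true(startsWith(m, applied) || startsWith(applied, m))
  }
  expect_error(call_indel(region, wt), "no variant")
})

test_that("complex alleles are rejected with both mismatch loci named", {
  # two separated substitutions cannot be a single contiguous indel
  mut <- wt
  substr(mut, 3, 3) <- "T"
  substr(mut, 30, 30) <- "A"
  expect_error(call_indel(region, mut), "complex allele.*position 3.*30")
})

test_that("protein consequences match the allele table", {
  expected <- list(
    i271 = list(kind = "frameshift", notation = "D250RfsX7",
                first = 250L, fsx = 7L),
    i272 = list(kind = "frameshift", notation = "F248SfsX59",
                first = 248L, fsx = 59L),
    i273 = list(kind = "inframe_deletion", notation = "D250del",
                first = 250L, fsx = NA_integer_))
  for (nm in names(expected)) {
    e <- expected[[nm]]
    call <- call_indel(region, fx$sequences[[nm]])
    pc <- protein_consequence(region, call, fx$sequences[[nm]])
    expect_identical(pc$kind, e$kind)
    expect_identical(pc$notation, e$notation)
    expect_identical(pc$first_affected_residue, e$first)
    expect_identical(pc$fs_stop_offset, e$fsx)
  }
  # frameshift peptide length consistency: k - 1 residues before the stop
  pc <- protein_consequence(region, call_indel(region, fx$sequences[["i272"]]),
                            fx$sequences[["i272"]])
  expect_identical(nchar(sub("\\*$", "", pc$mutant_peptide)),
                   pc$fs_stop_offset - 1L)
})

test_that("frameshift without an in-region stop is reported, not invented", {
  # delete 1 bp near the start of a stop-free frame
  reg <- target_region("ATGGCTGCTGCAGCAGCTGCA", cds_start_nt = 1L,
                       frame_offset = 0L, first_residue_number = 1L)
  mut <- paste0(substr(reg$sequence, 1, 5), substr(reg$sequence, 7,
                                                   nchar(reg$sequence)))
  pc <- protein_consequence(reg, call_indel(reg, mut), mut)
  expect_identical(pc$kind, "frameshift")
  expect_true(pc$stop_beyond_region)
  expect_true(is.na(pc$fs_stop_offset))
  expect_match(pc$notation, "fsX\\?$")
})

test_that("random single-indel mutants round-trip exactly", {
  set.seed(42)
  for (i in 1:300) {
    reg <- target_region(random_dna(60), cds_start_nt = 1L)
    rm_ <- random_indel_mutant(reg$sequence)
    if (rm_$mut == reg$sequence) next
    call <- call_indel(reg, rm_$mut)
    expect_identical(apply_indel(reg, call), rm_$mut)
    # rightmost placement must reconstruct the same mutant too
    call_r <- call_indel(reg, rm_$mut, policy = "rightmost")
    expect_identical(apply_indel(reg, call_r), rm_$mut)
    expect_identical(call$length_nt, call_r$length_nt)
  }
})

test_that("alignment policy places repeat-context indels 5' or 3'", {
  reg <- target_region("AACTTTTGAA", cds_start_nt = 1L)
  mut <- "AACTTTGAA" # one T of the TTTT run deleted
  l <- call_indel(reg, mut, policy = "leftmost")
  r <- call_indel(reg, mut, policy = "rightmost")
  expect_identical(l$position_nt, 4L)
  expect_identical(r$position_nt, 7L)
  expect_identical(apply_indel(reg, l), mut)
  expect_identical(apply_indel(reg, r), mut)
})

test_that("protein-level diff is placement-invariant for in-frame deletions", {
  # GCA GCA GCA repeat: deleting either AAG frame-crossing triplet or a
  # whole codon yields the same single-residue loss
  reg <- target_region("ATGGCAGCAGCATGG", cds_start_nt = 1L,
                       frame_offset = 0L, first_residue_number = 1L)
  mut <- "ATGGCAGCATGG"
  for (pol in c("leftmost", "rightmost")) {
    call <- call_indel(reg, mut, policy = pol)
    pc <- protein_consequence(reg, call, mut)
    expect_identical(pc$kind, "inframe_deletion")
    expect_identical(pc$notation, "A4del")
  }
})

test_that("frame arithmetic ties the nucleotide and protein coordinates", {
  for (nm in c("i271", "i272")) {
    call <- call_indel(region, fx$sequences[[nm]])
    pc <- protein_consequence(region, call, fx$sequences[[nm]])
    # first altered residue cannot precede the codon containing the indel
    codon_of_indel <- region$first_residue_number +
      (call$region_pos - 1L - region$frame_offset) %/% 3L
    expect_true(pc$first_affected_residue >= codon_of_indel)
    # stop offset counts residues within the translated mutant sequence
    mut_prot <- translate_region(region, fx$sequences[[nm]])
    r_idx <- pc$first_affected_residue - region$first_residue_number + 1L
    expect_identical(substr(mut_prot, r_idx + pc$fs_stop_offset - 1L,
                            r_idx + pc$fs_stop_offset - 1L), "*")
  }
})
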