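ped_fixture <- function(lines, map_lines) {
  ped <- withr::local_tempfile(fileext = ".ped", .local_envir = parent.frame())
  map <- withr::local_tempfile(fileext = ".map", .local_envir = parent.frame())
  writeLines(lines, ped)
  writeLines(map_lines, map)
  list(ped = ped, map = map)
}

test_that("dosages are counted against the founder minor allele", {
  fx <- ped_fixture(c(
    "F1 dad 0 0 1 1  G G  A A",
    "F1 mom 0 0 2 1  A G  A G",
    "F1 kid dad mom 1 2  A G  0 0",
    "F2 dad 0 0 1 1  G G  A G",
    "F2 mom 0 0 2 1  G G  G G",
    "F2 kid dad mom 2 2  G G  A G"),
    c("1 rs1 0 1000", "1 rs2 0 2000"))
  pan <- read_ped(fx$ped, fx$map)

  # rs1: founder alleles {G,G,A,G,G,G,G,G} -> minor A
  expect_equal(pan$snps$allele_minor[1], "A")
  expect_equal(pan$m[, 1], c(F1 = 1L, F2 = 0L))
  expect_equal(pan$f[, 1], c(F1 = 0L, F2 = 0L))
  expect_equal(pan$c[, 1], c(F1 = 1L, F2 = 0L))

  # rs2: "0 0" is missing; founder alleles tie 4 A / 4 G, so the ASCII-lowest
  # character (A) becomes the minor allele
  expect_equal(pan$snps$allele_minor[2], "A")
  expect_true(is.na(pan$c[1, 2]))
  expect_equal(pan$m[, 2], c(F1 = 1L, F2 = 0L))

  # both parents genotyped somewhere: present
  expect_true(all(pan$families$mother_present))
  expect_true(all(pan$families$father_present))
})

test_that("pedigree reader validates its input", {
  fx <- ped_fixture(c(
    "F1 dad 0 0 1 1 G G",
    "F1 mom 0 0 2 1 A G G"),        # 1 field too many
    "1 rs1 0 1000")
  expect_error(read_ped(fx$ped, fx$map), "line 2")

  fx <- ped_fixture(c(
    "F1 dad 0 0 1 1 G G",
    "F1 dad 0 0 2 1 A G",
    "F1 kid dad dad 1 2 A G"),
    "1 rs1 0 1000")
  expect_error(read_ped(fx$ped, fx$map), "duplicated individual ID")

  fx <- ped_fixture(c(
    "F1 dad 0 0 1 1 G G",
    "F1 mom 0 0 2 1 A G",
    "F1 kid dad mom 1 1 A G"),      # nobody affected
    "1 rs1 0 1000")
  expect_error(read_ped(fx$ped, fx$map), "no affected")

  fx <- ped_fixture("F1 kid 0 0 1 2 A X", "1 rs1 0 1000")
  expect_error(read_ped(fx$ped, fx$map), "allele code")

  # two affected children: first by individual ID kept, with a warning
  fx <- ped_fixture(c(
    "F1 mom 0 0 2 1 A G",
    "F1 dad 0 0 1 1 G G",
    "F1 zed dad mom 1 2 A A",
    "F1 abe dad mom 1 2 G G"),
    "1 rs1 0 1000")
  expect_warning(pan <- read_ped(fx$ped, fx$map), "affected children")
  expect_equal(unname(pan$c[1, 1]), 0L)   # abe (G G) kept, minor = A
})

test_that("panels round-trip through PED/MAP bit-identically", {
  pan <- simulate_panel(sim_config(n_families = 100, n_snps = 4,
                                   full_trio_fraction = 0.387,
                                   nocall_rate = 0.03, seed = 99))
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_ped(pan, ped, map)
  write_annotation(pan$snps, ann)
  back <- read_ped(ped, map, annotation = read_annotation(ann))

  expect_equal(unname(back$m), unname(pan$m))
  expect_equal(unname(back$f), unname(pan$f))
  expect_equal(unname(back$c), unname(pan$c))
  expect_equal(back$snps$allele_minor, pan$snps$allele_minor)
  expect_equal(back$families$mother_present, pan$families$mother_present)
  expect_equal(back$families$father_present, pan$families$father_present)

  # and written again, the files are identical
  ped2 <- withr::local_tempfile(fileext = ".ped")
  map2 <- withr::local_tempfile(fileext = ".map")
  write_ped(back, ped2, map2)
  expect_identical(readLines(ped2), readLines(ped))
  expect_identical(readLines(map2), readLines(map))
})

test_that("edge panels write correctly", {
  # empty panel -> valid empty files
  empty <- trio_panel(
    data.frame(snp_id = character(), chromosome = character(),
               position = integer(), allele_minor = character(),
               allele_major = character(), gene = character(),
               pathway = character()),
    data.frame(family_id = character(), stratum = character(),
               mother_present = logical(), father_present = logical()),
    matrix(NA_integer_, 0, 0), matrix(NA_integer_, 0, 0),
    matrix(NA_integer_, 0, 0))
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped(empty, ped, map)
  expect_equal(n_families(read_ped(ped, map)), 0L)

  # a homozygous-minor mother is written as two minor-allele characters
  one <- trio_panel(
    data.frame(snp_id = "rs9", chromosome = "2", position = 5L,
               allele_minor = "T", allele_major = "C", gene = "G1",
               pathway = "other"),
    data.frame(family_id = "F1", stratum = "ALL",
               mother_present = TRUE, father_present = TRUE),
    m = matrix(2L), f = matrix(0L), c = matrix(1L))
  write_ped(one, ped, map)
  mom <- grep(" 2 1 ", readLines(ped), value = TRUE)
  expect_match(mom, "T T$")
})

test_that("annotation tables parse with pathway normalisation", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchr\tpos\tminor\tmajor\tgene\tpathway",
               "rs6812588\t4\t101\tA\tG\tRFC1\tFolate",
               "rs1762430\t10\t202\tA\tG\tMGMT\tTranssulfuration",
               "rs0001\t1\t303\tC\tT\tFOO\txyz"), tsv)
  ann <- read_annotation(tsv)
  expect_equal(ann$pathway, c("folate", "transsulfuration", "other"))
  expect_equal(ann$gene[1], "RFC1")
  expect_equal(ann$chromosome[2], "10")

  writeLines(c("snp_id\tchr\tminor\tmajor\tgene\tpathway",
               "rs1\t1\tA\tG\tX\tfolate"), tsv)
  expect_error(read_annotation(tsv), "pos")

  # CRLF line endings tolerated
  writeLines(c("snp_id\tchr\tpos\tminor\tmajor\tgene\tpathway\r",
               "rs1\t1\t10\tA\tG\tX\thomocysteine\r"), tsv, sep = "\n")
  expect_equal(read_annotation(tsv)$pathway, "homocysteine")
})
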