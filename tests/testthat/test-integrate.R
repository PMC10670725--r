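test_that("negative-support rows are removed and duplicates collapsed", {
  tab <- tibble::tibble(
    mirna_id = c("hsa-miR-1", "hsa-miR-1", "hsa-miR-2", "hsa-miR-3"),
    gene_id = c("cfl2", "CFL2", "PCNA", "BID"),
    support_type = c("Functional MTI", "Functional MTI (Weak)",
                     "Negative", "non-Negative evidence"),
    database = c("miRTarBase", "TarBase", "miRTarBase", "miRecords"))
  out <- filter_validated(tab)
  # case-insensitive substring match on "negative" removes rows 3 and 4
  expect_equal(nrow(out), 1)
  expect_equal(out$mirna_id, "hsa-mir-1")
  expect_equal(out$gene_id, "CFL2")

  all_neg <- tibble::tibble(mirna_id = "m", gene_id = "g",
                            support_type = "negative")
  expect_equal(nrow(filter_validated(all_neg)), 0)
})

test_that("protein tables with conflicting directions are rejected", {
  ok <- tibble::tibble(gene_id = c("a", "A", "B"),
                       direction = c("up", "up", "down"))
  expect_equal(nrow(validate_protein_table(ok)), 2)
  bad <- tibble::tibble(gene_id = c("A", "a"), direction = c("up", "down"))
  expect_error(validate_protein_table(bad), "conflicting")
})

test_that("overlap groups are the four directional intersections", {
  degs <- list(up = c("U1", "U2", "U3"), down = c("D1", "D2", "D3"))
  prot <- tibble::tibble(
    gene_id = c("D1", "D2", "U1", "U2", "D3", "X9"),
    direction = c("down", "down", "up", "down", "up", "up"))
  g <- build_overlap_groups(degs, prot)
  expect_equal(g$down_down, c("D1", "D2"))
  expect_equal(g$up_up, "U1")
  expect_equal(g$up_down, "U2")
  expect_equal(g$down_up, "D3")
  # pairwise disjoint
  all_members <- c(g$down_down, g$up_up, g$up_down, g$down_up)
  expect_false(anyDuplicated(all_members) > 0)

  none <- build_overlap_groups(list(up = "A", down = "B"),
                               tibble::tibble(gene_id = "C", direction = "up"))
  expect_true(all(lengths(unclass(none)) == 0))
})

test_that("circuit assembly follows the three mechanism rules exactly", {
  dems <- list(up = c("m1", "m2"), down = c("m3"))
  groups <- structure(list(down_down = c("G1", "G2"), up_up = c("G3"),
                           up_down = c("G4"), down_up = c("G5")),
                      class = "overlap_groups")
  validated <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m3", "m3", "m3", "m1"),
    gene_id = c("G1", "G4", "G2", "G1", "G3", "G5", "G3"))
  circuits <- assemble_circuits(dems, groups, validated)

  expect_equal(circuits$RRC1$edges,
               tibble::tibble(mirna_id = c("m1", "m2"),
                              gene_id = c("G1", "G2")))
  expect_equal(circuits$RRC2$edges,
               tibble::tibble(mirna_id = "m1", gene_id = "G4"))
  expect_equal(circuits$IRC$edges,
               tibble::tibble(mirna_id = "m3", gene_id = "G3"))
  # down-miRNA edge to a down/down gene (m3 -> G1) appears in no circuit;
  # the mRNA-down/protein-up gene G5 forms no fourth circuit
  all_edges <- dplyr::bind_rows(purrr::map(circuits, "edges"))
  expect_false(any(all_edges$gene_id == "G5"))
  expect_false(any(all_edges$mirna_id == "m3" & all_edges$gene_id == "G1"))
  # up-miRNA edge m1 -> G3 (up/up gene) also excluded by the direction rule
  expect_false(any(all_edges$mirna_id == "m1" & all_edges$gene_id == "G3"))
})

test_that("assembly equals brute-force rule application on random toys", {
  set.seed(99)
  for (rep in 1:10) {
    mirnas <- paste0("m", 1:3)
    genes <- paste0("G", 1:4)
    mir_up <- sample(mirnas, 2)
    mir_down <- setdiff(mirnas, mir_up)
    assign_group <- sample(c("dd", "uu", "ud", "du"), 4, replace = TRUE)
    groups <- structure(list(down_down = genes[assign_group == "dd"],
                             up_up = genes[assign_group == "uu"],
                             up_down = genes[assign_group == "ud"],
                             down_up = genes[assign_group == "du"]),
                        class = "overlap_groups")
    all_pairs <- expand.grid(mirna_id = mirnas, gene_id = genes,
                             stringsAsFactors = FALSE)
    validated <- tibble::as_tibble(
      all_pairs[sample(nrow(all_pairs), 7), ])

    got <- assemble_circuits(list(up = mir_up, down = mir_down),
                             groups, validated)
    want <- brute_force_circuits(tolower(mir_up), tolower(mir_down),
                                 groups$down_down, groups$up_down,
                                 groups$up_up,
                                 dplyr::mutate(validated,
                                               mirna_id = tolower(mirna_id)))
    for (ct in c("RRC1", "RRC2", "IRC")) {
      expect_equal(as.data.frame(got[[ct]]$edges),
                   as.data.frame(want[[ct]]),
                   ignore_attr = TRUE)
    }
    # circuit edges never leave the validated table
    all_edges <- dplyr::bind_rows(purrr::map(got, "edges"))
    expect_true(all(paste(all_edges$mirna_id, all_edges$gene_id) %in%
                      paste(tolower(validated$mirna_id), validated$gene_id)))
  }
})

test_that("assembly is invariant to interaction row order", {
  dems <- list(up = c("m1", "m2"), down = "m3")
  groups <- structure(list(down_down = c("G1", "G2"), up_up = "G3",
                           up_down = character(0), down_up = character(0)),
                      class = "overlap_groups")
  validated <- tibble::tibble(mirna_id = c("m1", "m2", "m3", "m2"),
                              gene_id = c("G1", "G2", "G3", "G1"))
  a <- assemble_circuits(dems, groups, validated)
  b <- assemble_circuits(dems, groups, validated[sample(4), ])
  expect_equal(a$RRC1$edges, b$RRC1$edges)
  expect_equal(a$IRC$edges, b$IRC$edges)
  # idempotence: assembling from a circuit's own edges reproduces it
  c2 <- assemble_circuits(dems, groups, a$RRC1$edges)
  expect_equal(c2$RRC1$edges, a$RRC1$edges)
})

test_that("circuit summaries count edges and incident nodes", {
  empty <- regulatory_circuit("RRC1",
                              tibble::tibble(mirna_id = character(),
                                             gene_id = character()),
                              "up", "down", "down")
  expect_equal(unlist(circuit_summary(empty)[-1]),
               c(n_edges = 0L, n_mirnas = 0L, n_genes = 0L))

  star <- regulatory_circuit("RRC1",
                             tibble::tibble(mirna_id = "m1",
                                            gene_id = paste0("G", 1:5)),
                             "up", "down", "down")
  expect_equal(unlist(circuit_summary(star)[-1]),
               c(n_edges = 5L, n_mirnas = 1L, n_genes = 5L))

  set.seed(4)
  edges <- tibble::tibble(mirna_id = sample(paste0("m", 1:4), 8, TRUE),
                          gene_id = sample(paste0("G", 1:5), 8, TRUE)) |>
    dplyr::distinct()
  rc <- regulatory_circuit("IRC", edges, "down", "up", "up")
  s <- circuit_summary(rc)
  expect_equal(s$n_edges, nrow(edges))
  expect_equal(s$n_mirnas, length(unique(edges$mirna_id)))
  expect_equal(s$n_genes, length(unique(edges$gene_id)))
})
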