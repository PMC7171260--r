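# structure carrying the five named buried-acid positions used in
# protease mutation scans, plus basics, as isolated far-apart residues
pepsin_like_sites <- function() {
  mk <- function(kind, resnum, xoff) {
    tpl <- phstab:::template_atoms(kind)
    data.frame(atom = rownames(tpl), resname = kind, chain = "A",
               resnum = resnum, x = tpl[, 1] + xoff, y = tpl[, 2],
               z = tpl[, 3])
  }
  spec <- list(c("ASP", 96), c("GLU", 107), c("ASP", 149), c("ASP", 215),
               c("ASP", 303), c("LYS", 12), c("ARG", 44), c("HIS", 80))
  rows <- do.call(rbind, lapply(seq_along(spec), function(i) {
    mk(spec[[i]][1], as.integer(spec[[i]][2]), 20 * i)
  }))
  extract_ionisable_sites(parse_structure(phstab:::rows_to_pdb(rows)))
}

test_that("mutation rules remove exactly the selected sites", {
  sites <- pepsin_like_sites()

  basic <- apply_mutations(sites, mutation_rule("basic"))
  expect_equal(nrow(basic), 5L)
  expect_true(all(basic$kind %in% c("ASP", "GLU")))
  expect_equal(nrow(attr(basic, "removed")), 3L)

  expl <- apply_mutations(sites, mutation_rule(
    c("A/D96", "A/E107", "A/D149", "A/D215", "A/D303")))
  expect_equal(nrow(attr(expl, "removed")), 5L)
  expect_true(all(expl$kind %in% c("LYS", "ARG", "HIS")))

  # untouched sites keep identical rows
  expect_equal(basic, sites[sites$kind %in% c("ASP", "GLU"), ],
               ignore_attr = TRUE)
  # empty rule list is the identity
  expect_equal(apply_mutations(sites, list()), sites, ignore_attr = TRUE)
  expect_error(apply_mutations(sites, mutation_rule("A/D999")),
               "A/D999")
})

test_that("rule config lines parse to the same selections", {
  rules <- parse_mutation_rules(c("# comment", "mutate: basic->neutral"))
  sites <- pepsin_like_sites()
  expect_equal(apply_mutations(sites, rules),
               apply_mutations(sites, mutation_rule("basic")))
  r2 <- parse_mutation_rules("mutate: A/D96,A/E107->neutral")
  expect_equal(nrow(attr(apply_mutations(sites, r2), "removed")), 2L)
  expect_error(parse_mutation_rules("mutate basic"), "parse")
})

test_that("removing all basics forces a non-positive titration charge", {
  toy <- parse_structure(make_toy_domain(toy_spec(40, 4, 0)))
  sites <- extract_ionisable_sites(toy)
  mut <- apply_mutations(sites, mutation_rule("basic"))
  W <- build_interaction_matrix(mut)
  tr <- enumerate_titration(mut, W)
  expect_true(all(tr$mean_charge <= 1e-12))
})

test_that("burial classification follows relative sidechain accessibility", {
  exposed <- parse_structure(phstab:::make_single_residue("ASP"))
  expect_equal(nrow(buried_acidic_sites(exposed)), 0L)
  caged <- parse_structure(caged_residue_pdb("ASP"))
  hit <- buried_acidic_sites(caged)
  expect_equal(hit$resname, "ASP")
  expect_equal(nrow(buried_acidic_sites(caged, rel_threshold = 0)), 0L)
})

test_that("salt-bridge detection obeys its distance cutoff", {
  near <- parse_structure(make_pair("ASP", "LYS", 4))
  sites <- extract_ionisable_sites(near)
  # centre separation 4 A: minimum O..NZ atom distance is below 4
  sb <- find_salt_bridges(near)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$class, "salt_bridge")

  far <- parse_structure(make_pair("ASP", "LYS", 9))
  expect_equal(nrow(find_salt_bridges(far)), 0L)

  # detection agrees with a brute-force all-pair scan on a toy domain
  toy <- parse_structure(make_toy_domain(toy_spec(40, 4, 2)))
  got <- find_salt_bridges(toy)
  basic_sel <- function(at) paste(at$resname, at$atom) %in%
    c("LYS NZ", "ARG NH1", "ARG NH2", "ARG NE", "HIS ND1", "HIS NE2")
  want <- brute_contacts(toy, acid_o_atoms, basic_sel, 4.0)
  expect_equal(nrow(got), nrow(want))
  expect_equal(sort(paste(got$acid_resnum, got$partner_resnum)),
               sort(paste(want$acid_resnum, want$partner_resnum)))
  expect_equal(sort(got$distance), sort(want$distance), tolerance = 1e-9)
})

test_that("carboxylate hydrogen-bond networks are classed by partner type", {
  q <- parse_structure(make_pair("ASP", "GLN", 4))
  hb <- carboxylate_hbond_network(q)
  expect_true("sidechain_hbond" %in% hb$class)
  expect_equal(hb$partner_atom[hb$class == "sidechain_hbond"], "NE2")

  toy <- parse_structure(make_toy_domain(toy_spec(40, 0, 4)))
  hb2 <- carboxylate_hbond_network(toy)
  expect_equal(sum(hb2$class == "sidechain_hbond"), 4L)
  expect_equal(sum(hb2$class == "mainchain_hbond"), 4L)

  # mainchain partners agree with brute force
  mc_sel <- function(at) at$atom == "N"
  want <- brute_contacts(toy, acid_o_atoms, mc_sel, 3.5)
  got_mc <- hb2[hb2$class == "mainchain_hbond", ]
  expect_equal(sort(paste(got_mc$acid_resnum, got_mc$partner_resnum)),
               sort(paste(want$acid_resnum, want$partner_resnum)))

  none <- parse_structure(make_pair("ASP", "GLN", 8))
  expect_equal(nrow(carboxylate_hbond_network(none)), 0L)
})

test_that("network summaries count per carboxylate and sort stably", {
  expect_equal(nrow(network_summary(phstab:::empty_contacts())), 0L)

  toy <- parse_structure(make_toy_domain(toy_spec(60, 2, 2)))
  recs <- dplyr::bind_rows(find_salt_bridges(toy),
                           carboxylate_hbond_network(toy))
  summ <- network_summary(recs)
  # hand tally: bridge acids have 1 contact, swap acids have 2
  expect_equal(summ$total,
               sort(summ$n_salt_bridge + summ$n_sidechain_hbond +
                      summ$n_mainchain_hbond, decreasing = TRUE))
  swap_rows <- summ[summ$total == 2, ]
  expect_equal(nrow(swap_rows), 2L)
  expect_equal(swap_rows$n_sidechain_hbond, c(1L, 1L))
  expect_equal(swap_rows$n_mainchain_hbond, c(1L, 1L))
  # ties sort by ascending residue number
  bridge_rows <- summ[summ$total == 1, ]
  expect_equal(bridge_rows$resnum, sort(bridge_rows$resnum))
  # zero-count acids appear when the site table is supplied
  sites <- extract_ionisable_sites(toy)
  with_sites <- network_summary(recs[recs$class == "salt_bridge", ], sites)
  expect_equal(nrow(with_sites), sum(sites$kind %in% c("ASP", "GLU")))
})
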