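sel_a <- selection(chain = "A")
sel_b <- selection(chain = "B")

test_that("donor/acceptor typing follows the chemistry table", {
  ser <- atom_df("A", 1, "SER", "OG", c(0, 0, 0))
  ty <- donors_acceptors(ser)
  expect_true(ty$donor && ty$acceptor)
  o <- donors_acceptors(atom_df("A", 1, "GLY", "O", c(0, 0, 0)))
  expect_false(o$donor); expect_true(o$acceptor)
  arg <- donors_acceptors(do.call(rbind, lapply(
    c("NE", "NH1", "NH2"),
    function(el) atom_df("A", 1, "ARG", el, stats::rnorm(3)))))
  expect_equal(sum(arg$donor), 3L)
  # proline backbone N has no hydrogen to donate
  pro <- donors_acceptors(atom_df("A", 1, "PRO", "N", c(0, 0, 0)))
  expect_equal(nrow(pro), 0L)
  expect_warning(donors_acceptors(atom_df("A", 1, "XYZ", "O1", c(0, 0, 0))),
                 "non-standard")
})

test_that("hydrogen bonds obey the distance and antecedent-angle rules", {
  expect_equal(nrow(find_hbonds(make_interaction_fixture("hbond_pair"),
                                sel_a, sel_b)), 1L)
  expect_equal(nrow(find_hbonds(
    make_interaction_fixture("hbond_pair", distance = 4.5), sel_a, sel_b)),
    0L)
  # acceptor tucked behind the donor antecedent fails the angle rule
  expect_equal(nrow(find_hbonds(
    make_interaction_fixture("hbond_pair", angle = 60), sel_a, sel_b)), 0L)
  rec <- find_hbonds(make_interaction_fixture("hbond_pair", distance = 3.1),
                     sel_a, sel_b)
  expect_equal(rec$distance, 3.1, tolerance = 1e-6)
  expect_equal(rec$atom_a, "OG")
})

test_that("salt bridges pair guanidinium with carboxylate", {
  sb <- find_salt_bridges(make_interaction_fixture("salt_bridge_pair"),
                          sel_a, sel_b)
  expect_equal(nrow(sb), 2L)
  expect_setequal(sb$atom_a, c("NH1", "NH2"))
  expect_setequal(sb$atom_b, c("OD1", "OD2"))
  expect_equal(nrow(find_salt_bridges(
    make_interaction_fixture("salt_bridge_pair", distance = 5.5),
    sel_a, sel_b)), 0L)
})

test_that("cation-pi requires proximity and elevation above the ring", {
  expect_equal(nrow(find_cation_pi(make_interaction_fixture("cation_pi"),
                                   sel_a, sel_b)), 1L)
  expect_equal(nrow(find_cation_pi(
    make_interaction_fixture("cation_pi", angle = 30), sel_a, sel_b)), 0L)
  expect_equal(nrow(find_cation_pi(
    make_interaction_fixture("cation_pi", angle = 0), sel_a, sel_b)), 0L)
  expect_equal(nrow(find_cation_pi(
    make_interaction_fixture("cation_pi", distance = 7), sel_a, sel_b)), 0L)
})

test_that("vdW contacts use the window and deduplicate per residue pair", {
  two_c <- function(d) {
    structure3d(rbind(
      atom_df("A", 1, "ALA", "CB", c(0, 0, 0)),
      atom_df("A", 1, "ALA", "CA", c(-2, 0, 0)),
      atom_df("B", 1, "LEU", "CD1", c(d, 0, 0)),
      atom_df("B", 1, "LEU", "CD2", c(d + 0.3, 1, 0))), id = "vdw")
  }
  v <- find_vdw_contacts(two_c(3.8), sel_a, sel_b)
  expect_equal(nrow(v), 1L)          # one record per residue pair
  expect_equal(v$distance, 3.8, tolerance = 1e-9)
  expect_equal(nrow(find_vdw_contacts(two_c(4.6), sel_a, sel_b)), 0L)
  expect_equal(nrow(find_vdw_contacts(two_c(2.5), sel_a, sel_b)), 0L)
})

test_that("water bridges need two polar contacts, one on the interface", {
  wb <- find_water_bridges(make_interaction_fixture("water_bridge"),
                           sel_a, sel_b, site_center = c(0, 0, 0))
  expect_equal(nrow(wb), 1L)
  expect_match(wb$waters, "HOH")
  # pull the protein-side nitrogen out of reach -> single contact, no bridge
  far <- make_interaction_fixture("water_bridge")
  idx <- far$atoms$elety == "N"
  far$atoms$x[idx] <- far$atoms$x[idx] + 10
  expect_equal(nrow(find_water_bridges(far, sel_a, sel_b, c(0, 0, 0))), 0L)
  # out-of-site waters are not counted
  expect_equal(nrow(find_water_bridges(
    make_interaction_fixture("water_bridge"), sel_a, sel_b,
    site_center = c(50, 0, 0))), 0L)
  dry <- subset_structure(make_interaction_fixture("water_bridge"),
                          selection(water = FALSE))
  expect_warning(out <- find_water_bridges(dry, sel_a, sel_b, c(0, 0, 0)),
                 "no waters")
  expect_equal(nrow(out), 0L)
})

composite_fixture <- function() {
  shift <- function(st, dz) {
    st$atoms$z <- st$atoms$z + dz
    st$atoms
  }
  at <- rbind(
    shift(make_interaction_fixture("hbond_pair"), 0),
    shift(make_interaction_fixture("salt_bridge_pair"), 50),
    shift(make_interaction_fixture("cation_pi"), 100),
    shift(make_interaction_fixture("water_bridge"), 150),
    atom_df("A", 9, "ALA", "CB", c(0, 0, 200)),
    atom_df("B", 9, "LEU", "CD1", c(3.8, 0, 200))
  )
  at$resno <- at$resno + match(round(at$z / 50), 0:4) * 10L
  structure3d(at, id = "composite")
}

test_that("the fingerprint unions all kinds and sorts by peptide residue", {
  st <- composite_fixture()
  fp <- fingerprint(st, sel_a, sel_b, site_center = c(0, 0, 150))
  expect_s3_class(fp, "interaction_table")
  expect_setequal(unique(fp$kind),
                  c("hbond", "salt_bridge", "cation_pi", "vdw",
                    "water_bridge"))
  resno_a <- as.integer(gsub("[^0-9]", "", fp$res_a))
  expect_false(is.unsorted(resno_a))
  # empty interface -> empty table
  empty <- fingerprint(st, selection(chain = "A", resno = 9999),
                       selection(chain = "B", resno = 9998))
  expect_equal(nrow(empty), 0L)
  # serialisation round trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(fp, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(fp))
  json <- withr::local_tempfile(fileext = ".json")
  write_interactions(fp, json)
  expect_equal(length(jsonlite::read_json(json)), nrow(fp))
})

test_that("all finders are symmetric under selection swap", {
  st <- composite_fixture()
  swap_key <- function(tab) {
    paste(tab$kind, pmin(tab$res_a, tab$res_b), pmax(tab$res_a, tab$res_b),
          round(tab$distance, 6))
  }
  for (f in list(find_hbonds, find_salt_bridges, find_cation_pi,
                 find_vdw_contacts)) {
    ab <- f(st, sel_a, sel_b)
    ba <- f(st, sel_b, sel_a)
    expect_setequal(swap_key(ab), swap_key(ba))
  }
  wab <- find_water_bridges(st, sel_a, sel_b, c(0, 0, 150))
  wba <- find_water_bridges(st, sel_b, sel_a, c(0, 0, 150))
  expect_equal(nrow(wab), nrow(wba))
  expect_error(find_hbonds(st, sel_a, sel_a), "disjoint")
})

test_that("tightening any distance criterion never grows the record set", {
  st <- composite_fixture()
  loose <- interaction_criteria()
  tight <- interaction_criteria(hbond_max_da = 2.9, salt_bridge_max = 3.2,
                                vdw_max = 3.9, cation_pi_max_centroid = 4.5,
                                water_contact_max = 3.0)
  for (f in list(find_hbonds, find_salt_bridges, find_cation_pi,
                 find_vdw_contacts)) {
    expect_lte(nrow(f(st, sel_a, sel_b, tight)),
               nrow(f(st, sel_a, sel_b, loose)))
  }
})

test_that("cell-binned neighbour search matches the brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(stats::runif(3 * 300, 0, 20), ncol = 3)
    B <- matrix(stats::runif(3 * 400, 0, 20), ncol = 3)
    for (cutoff in c(1.5, 4)) {
      fast <- wins7:::close_pairs(A, B, cutoff, method = "cell")
      slow <- wins7:::close_pairs(A, B, cutoff, method = "brute")
      expect_equal(fast$i, slow$i)
      expect_equal(fast$j, slow$j)
      expect_equal(fast$dist, slow$dist, tolerance = 1e-12)
    }
  }
})
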