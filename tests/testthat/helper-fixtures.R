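# Shared helpers for building tiny structures in tests.

atom_df <- function(chain, resno, resid, elety, xyz, hetero = FALSE) {
  wins7:::atom_row(chain, resno, resid, elety, xyz, hetero = hetero)
}

# A minimal WDR5-like anchor set: aromatic rings at 133/149, Pro173 CA,
# Tyr191 with ring, plus backbone carbonyl O at 91/133/261.
mini_propeller <- function() {
  hexagon <- function(centre, normal_axis = "z") {
    ang <- c(0, 60, 120, 180, 240, 300)
    names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    do.call(rbind, lapply(seq_along(ang), function(i) {
      a <- ang[i] * pi / 180
      centre + 1.39 * c(cos(a), sin(a), 0)
    })) -> xyz
    list(names = names, xyz = xyz)
  }
  rows <- list()
  add <- function(chain, resno, resid, elety, xyz) {
    rows[[length(rows) + 1L]] <<- atom_df(chain, resno, resid, elety, xyz)
  }
  h <- hexagon(c(0, 0, 0))
  for (i in seq_along(h$names)) add("A", 133, "PHE", h$names[i], h$xyz[i, ])
  add("A", 133, "PHE", "O", c(2, 4, 1))
  h <- hexagon(c(8, 0, 0))
  for (i in seq_along(h$names)) add("A", 149, "PHE", h$names[i], h$xyz[i, ])
  add("A", 173, "PRO", "CA", c(4, 8, 0))
  add("A", 191, "TYR", "CB", c(4, 4, 6))
  h <- hexagon(c(4, 4, 8))
  for (i in seq_along(h$names)) add("A", 191, "TYR", h$names[i], h$xyz[i, ])
  add("A", 91, "SER", "O", c(0, 4, 1))
  add("A", 261, "CYS", "O", c(4, 0, 1))
  structure3d(do.call(rbind, rows), id = "mini_propeller")
}
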