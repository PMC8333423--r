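# small in-code fixtures shared across test files

two_tet_mesh <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)),
           rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)),
           node_sets = list(base = c(1L, 2L, 3L)))
}

unit_tet_mesh <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(c(1, 2, 3, 4), 1))
}

# two unit boxes far apart in a single mesh: a disconnected "mechanism"
disconnected_mesh <- function() {
  m1 <- generate_box_mesh(c(1, 1, 1), c(1, 1, 1))
  m2 <- generate_box_mesh(c(1, 1, 1), c(1, 1, 1))
  nodes <- rbind(m1$nodes, sweep(m2$nodes, 2, c(5, 0, 0), "+"))
  tets <- rbind(m1$tets, m2$tets + nrow(m1$nodes))
  tet_mesh(nodes, tets)
}

# asymmetric cantilever (distinct section sides, distinct eigenvalues):
# used wherever individual modes must be comparable across runs
asym_cantilever_system <- function(divisions = c(6, 2, 3), rho = 1.0,
                                   lengths = c(60, 8, 12)) {
  mesh <- generate_box_mesh(lengths, divisions)
  mat <- build_material_field(mesh, rho)
  list(mesh = mesh, material = mat,
       system = assemble(mesh, mat, bc_spec("FEMP-I", fixed_sets = "xmin")))
}
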