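# Shared fixtures, built in code at test time.

# fixed-width PDB ATOM/HETATM line (enough columns for bio3d)
pdb_line <- function(record, serial, name, alt, resname, chain, resno,
                     x, y, z) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, alt, resname, chain, resno, x, y, z, 1, 0)
}

# 3-residue toy structure with an altloc'd atom and a zinc HETATM
write_toy_pdb <- function(path) {
  lines <- c(
    pdb_line("ATOM", 1, " N", "", "ALA", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 2, " CA", "", "ALA", "A", 1, 1.5, 0, 0),
    pdb_line("ATOM", 3, " CA", "A", "GLY", "A", 2, 4.0, 0, 0),
    pdb_line("ATOM", 4, " CA", "B", "GLY", "A", 2, 9.0, 9, 9),
    pdb_line("ATOM", 5, " CA", "", "MLY", "A", 3, 7.5, 0, 0),
    pdb_line("HETATM", 6, "ZN", "", "ZN", "A", 9, 3.0, 2, 0),
    "END")
  writeLines(lines, path)
  path
}

# benchmark at compact study-like settings, generated once per test run
.bench_env <- new.env()
get_benchmark <- function() {
  if (is.null(.bench_env$bm)) {
    dir <- file.path(tempdir(), "bt_bench_small")
    cfg <- plant_config(n_xgroups = 6, domains_per_group = 2, n_themes = 4,
                        ligand_fraction = 1, seed = 42)
    .bench_env$bm <- generate_benchmark(cfg, dir)
    .bench_env$dir <- dir
    .bench_env$cfg <- cfg
  }
  .bench_env$bm
}
get_benchmark_dir <- function() {
  get_benchmark()
  .bench_env$dir
}

# random sequences over the full alphabet
rand_seq <- function(n) paste(sample(c("A","C","D","E","F","G","H","I","K",
                                       "L","M","N","P","Q","R","S","T","V",
                                       "W","Y"), n, TRUE), collapse = "")
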