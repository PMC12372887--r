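# Raw-text structure fixtures built in code.

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resn, chain, resno, x, y, z, occ, 0, element)
}

write_pdb_fixture <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

# same atoms expressed as a minimal mmCIF atom_site loop
write_cif_fixture <- function(df, file = tempfile(fileext = ".cif")) {
  head <- c("data_fixture", "loop_",
            paste0("_atom_site.",
                   c("group_PDB", "id", "type_symbol", "label_atom_id",
                     "label_alt_id", "label_comp_id", "label_asym_id",
                     "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                     "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                     "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                     "auth_comp_id", "auth_asym_id", "auth_atom_id",
                     "pdbx_PDB_model_num")))
  rows <- sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
                  seq_len(nrow(df)), df$element, df$elety, df$resid,
                  df$chain, df$resno, df$x, df$y, df$z, 1, df$resno,
                  df$resid, df$chain, df$elety)
  writeLines(c(head, rows), file)
  file
}

write_panel_fixture <- function(df, file = tempfile(fileext = ".csv")) {
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  file
}
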