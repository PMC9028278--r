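# Shared fixtures, all built in code.

jb1 <- function() cyclic_peptide("JB1", "CYAAPLKPAKSC", "head_to_tail")

somatostatin <- function() {
  cyclic_peptide("somatostatin", "AGCKNFFWKTFTSC", "disulfide",
                 disulfide_pair = c(3, 14))
}

# reduced-size synthetic dataset for fast I/O and pipeline tests;
# chemistry-level defaults are left at the generator's standard values
small_sim <- function(seed = 1L, sites = data.frame(site = 11L, abundance = 1),
                      parent = jb1(), ...) {
  simulate_runs(synth_config(parent, true_opening_sites = sites,
                             rt_range = c(1, 4), matrix_ion_count = 20L,
                             seed = seed, ...))
}

# a bare spectrum from explicit peaks
spec_from_peaks <- function(mz, intensity, time = 1, sf = "targeted_msms",
                            precursor = NA_real_) {
  ms_spectrum("scan=1", time, if (sf == "full") 1L else 2L, sf,
              mz = mz, intensity = intensity, precursor_mz = precursor)
}

# minimal empty-but-valid mzML document
write_empty_mzml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="empty">',
    '  <cvList count="1">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '  </cvList>',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '    </fileContent>',
    '  </fileDescription>',
    '  <softwareList count="1">',
    '    <software id="sw" version="1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software>',
    '  </softwareList>',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration>',
    '  </instrumentConfigurationList>',
    '  <dataProcessingList count="1">',
    '    <dataProcessing id="dp">',
    '      <processingMethod order="0" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod>',
    '    </dataProcessing>',
    '  </dataProcessingList>',
    '  <run id="r" defaultInstrumentConfigurationRef="IC">',
    '    <spectrumList count="0" defaultDataProcessingRef="dp"/>',
    '  </run>',
    '</mzML>'), path)
  path
}
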