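>amTOR_site_synthetic miR162a target-site stand-in: reverse complement of miR162a with one seed G:U wobble and a central 2x2 internal loop (synthetic; not the published transcript sequence)
CUGGAUGCAGCAGUUUAUUGA
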