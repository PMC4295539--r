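<interface>
  <currenttask name="import_structural" domain="subject"
               desc="Import the structural volume" modality="MRI">
    <permanenceofoutput>2</permanenceofoutput>
    <outputstreams><stream>structural</stream></outputstreams>
  </currenttask>
</interface>
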