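<interface>
  <currenttask name="import_epi" domain="session"
               desc="Import a 4D EPI series and discard dummy scans" modality="MRI">
    <qsub><memoryBase>0.2</memoryBase><timeBase>0.1</timeBase></qsub>
    <permanenceofoutput>1</permanenceofoutput>
    <numdummies>0</numdummies>
    <outputstreams><stream>epi</stream></outputstreams>
  </currenttask>
</interface>
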