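<interface>
  <currenttask name="check_parameters" domain="study"
               desc="Validate the study description and input locations" modality="MRI">
    <permanenceofoutput>0</permanenceofoutput>
  </currenttask>
</interface>
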