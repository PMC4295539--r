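<tasklist>
  <initialisation>
    <module><name>check_parameters</name></module>
  </initialisation>
  <main>
    <module><name>import_epi</name></module>
    <module><name>realign</name></module>
    <branch>
      <alternative analysisid_suffix="_smo8">
        <module>
          <name>smooth</name>
          <settings><FWHM>8</FWHM></settings>
        </module>
        <module><name>first_level</name></module>
        <module><name>second_level</name></module>
      </alternative>
      <alternative analysisid_suffix="_smo12">
        <module>
          <name>smooth</name>
          <settings><FWHM>12</FWHM></settings>
        </module>
        <module><name>first_level</name></module>
        <module><name>second_level</name></module>
      </alternative>
    </branch>
  </main>
</tasklist>
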