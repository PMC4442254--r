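<?xml version="1.0" encoding="UTF-8"?>
<article id="example-1" journal="Zootaxa" year="2011" doi="10.9999/example.1" pageCount="34">
  <meta>
    <author>T. Kronestedt</author>
    <author>Y. Marusik</author>
  </meta>
  <treatment id="example-1-t1" rank="species" status="sp. nov.">
    <taxon orderEpithet="Araneae" familyEpithet="Lycosidae" genusEpithet="Pardosa" speciesEpithet="exemplaris"/>
    <materialsCitation country="Russia" locality="Magadan area" elevation="1250" date="1999-07-12" collectorName="Y. Marusik" typeStatus="holotype">
      <collectionCode>ZMMU</collectionCode>
      <specimenCount type="male" count="1"/>
      <specimenCount type="total" count="1"/>
      <specimenCode>ZMMU-TA-1001</specimenCode>
    </materialsCitation>
    <materialsCitation country="Mongolia" locality="type locality" date="1999-07" collectorName="Y. Marusik &amp; D. Obydov" typeStatus="paratype">
      <collectionCode>ZMMU</collectionCode>
      <collectionCode>IBPN</collectionCode>
      <collectionCode>ISEA</collectionCode>
      <specimenCount type="male" count="110"/>
      <specimenCount type="female" count="44"/>
      <specimenCount type="total" count="154"/>
    </materialsCitation>
  </treatment>
  <treatment id="example-1-t2" rank="genus">
    <taxon orderEpithet="Araneae" familyEpithet="Lycosidae" genusEpithet="Pardosa"/>
  </treatment>
</article>
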