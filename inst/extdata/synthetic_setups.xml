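<?xml version="1.0" encoding="UTF-8"?>
<setups>
  <setup id="clinic1_1" clinic="clinic1">
    <instrument id="inst01" label="inst01" x="1495.7817135014452" y="153.73240644462243" angle="336.36949229337671"/>
    <instrument id="inst02" label="inst02" x="19.147498559211478" y="652.89225942354358" angle="215.17213372155939"/>
    <instrument id="inst03" label="inst03" x="61.537834050256791" y="1022.9235624413745" angle="101.35749176645754"/>
    <instrument id="inst04" label="inst04" x="1545.6000601482485" y="795.3847410465969" angle="50.415508054109281"/>
    <instrument id="inst05" label="inst05" x="435.20145815400218" y="766.85365797214661" angle="320.67627312041782"/>
    <instrument id="inst06" label="inst06" x="1909.0379119230956" y="927.44353919369428" angle="67.976009575904982"/>
  </setup>
  <setup id="clinic1_2" clinic="clinic1">
    <instrument id="inst01" label="inst01" x="1472.182242647124" y="127.62000287093876" angle="338.101518816034"/>
    <instrument id="inst02" label="inst02" x="21.124450144710764" y="653.21967617570158" angle="218.31366456024173"/>
    <instrument id="inst03" label="inst03" x="85.761584736896012" y="1032.635360838636" angle="91.373000093943674"/>
    <instrument id="inst04" label="inst04" x="1566.2158359627135" y="795.83529097860207" angle="29.838829531554612"/>
    <instrument id="inst05" label="inst05" x="433.4661443335109" y="770.68457728421242" angle="315.12581913877801"/>
    <instrument id="inst06" label="inst06" x="1904.5529745284825" y="914.61904558868207" angle="79.406519488888776"/>
  </setup>
  <setup id="clinic2_1" clinic="clinic2">
    <instrument id="inst01" label="inst01" x="1048.6464857312455" y="801.51049156627721" angle="342.22719988408727"/>
    <instrument id="inst02" label="inst02" x="1839.1183261959955" y="972.45171430719711" angle="208.07271625563232"/>
    <instrument id="inst03" label="inst03" x="1756.0524104847705" y="597.44347608346459" angle="96.850809323530456"/>
    <instrument id="inst04" label="inst04" x="1791.9768798524838" y="462.60353581671728" angle="282.57091745283464"/>
    <instrument id="inst05" label="inst05" x="1279.8846929919309" y="687.78720420134391" angle="32.614212629265182"/>
    <instrument id="inst06" label="inst06" x="1917.7027710313289" y="431.53455421628178" angle="312.03436575977355"/>
  </setup>
  <setup id="clinic2_2" clinic="clinic2">
    <instrument id="inst01" label="inst01" x="1052.7549830180255" y="813.16357857452761" angle="324.7815804339856"/>
    <instrument id="inst02" label="inst02" x="1817.0945421434426" y="961.07088046347758" angle="205.87427413882054"/>
    <instrument id="inst03" label="inst03" x="1742.2940771319936" y="586.54738239975404" angle="106.30715234682404"/>
    <instrument id="inst04" label="inst04" x="1773.1650842765462" y="450.73339200129527" angle="304.29342625236626"/>
    <instrument id="inst05" label="inst05" x="1283.0613407096816" y="708.42981749998137" angle="40.988548805931501"/>
    <instrument id="inst06" label="inst06" x="1919.2351312612973" y="430.97068738795122" angle="329.20459077567847"/>
  </setup>
</setups>
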