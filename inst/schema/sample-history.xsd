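<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema for the XML rendering of a sample history report: the ordered
     experimental stages that led to a sample, plus the DOT source of its
     workflow diagram. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:element name="sample-history">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="stage" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="experiment">
                <xs:complexType>
                  <xs:attribute name="id" type="xs:string" use="required"/>
                  <xs:attribute name="name" type="xs:string"/>
                  <xs:attribute name="performed-at" type="xs:string"/>
                </xs:complexType>
              </xs:element>
              <xs:element name="protocol">
                <xs:complexType>
                  <xs:attribute name="name" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
              <xs:element name="parameters">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="parameter" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:simpleContent>
                          <xs:extension base="xs:string">
                            <xs:attribute name="name" type="xs:string" use="required"/>
                            <xs:attribute name="phase">
                              <xs:simpleType>
                                <xs:restriction base="xs:string">
                                  <xs:enumeration value="setup"/>
                                  <xs:enumeration value="result"/>
                                </xs:restriction>
                              </xs:simpleType>
                            </xs:attribute>
                          </xs:extension>
                        </xs:simpleContent>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="inputs" type="sampleList"/>
              <xs:element name="outputs" type="sampleList"/>
            </xs:sequence>
            <xs:attribute name="index" type="xs:positiveInteger" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="workflow">
          <xs:complexType>
            <xs:simpleContent>
              <xs:extension base="xs:string">
                <xs:attribute name="format" type="xs:string" fixed="dot"/>
              </xs:extension>
            </xs:simpleContent>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="subject" type="xs:string" use="required"/>
      <xs:attribute name="subject-type" type="xs:string"/>
      <xs:attribute name="stages" type="xs:nonNegativeInteger"/>
    </xs:complexType>
  </xs:element>
  <xs:complexType name="sampleList">
    <xs:sequence>
      <xs:element name="sample" minOccurs="0" maxOccurs="unbounded">
        <xs:complexType>
          <xs:attribute name="id" type="xs:string" use="required"/>
          <xs:attribute name="type" type="xs:string"/>
          <xs:attribute name="label" type="xs:string"/>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>
</xs:schema>
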